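# Imprinted-gene matching and ICR interval mapping.

test_that("half-open BED boundaries are respected for probe positions", {
  ann <- data.frame(probe_id = c("a", "b", "c"), chr = "1",
                    pos = c(100, 150, 50), stringsAsFactors = FALSE)
  icrs <- data.frame(chr = "1", start = 50, end = 150, gene = "G1",
                     origin = "paternal", stringsAsFactors = FALSE)
  dmcs <- data.frame(probe_id = c("a", "b", "c"))
  hits <- map_icrs(dmcs, ann, icrs)$hits
  # [50, 150): pos 100 hits, pos 150 does not (half-open), pos 50 does
  expect_setequal(hits$probe_id, c("a", "c"))
})

test_that("interval lookup agrees with the brute-force all-pairs oracle", {
  set.seed(14)
  n_probes <- 1000; n_icrs <- 120
  ann <- data.frame(
    probe_id = sprintf("p%04d", seq_len(n_probes)),
    chr = sample(c("1", "2", "X"), n_probes, replace = TRUE),
    pos = sample.int(50000, n_probes, replace = TRUE),
    stringsAsFactors = FALSE)
  starts <- sample.int(49000, n_icrs, replace = TRUE)
  icrs <- data.frame(
    chr = sample(c("1", "2", "X"), n_icrs, replace = TRUE),
    start = starts, end = starts + sample.int(800, n_icrs, replace = TRUE),
    gene = sprintf("G%03d", seq_len(n_icrs)),
    origin = sample(c("paternal", "maternal", "unknown"), n_icrs,
                    replace = TRUE),
    stringsAsFactors = FALSE)
  dmcs <- data.frame(probe_id = ann$probe_id)

  got <- map_icrs(dmcs, ann, icrs)$hits
  want <- overlap_oracle(ann, icrs)
  key <- function(d) sort(paste(d$probe_id, d$icr_id))
  expect_identical(key(got), key(want))

  # counts invariant under row shuffles of both inputs
  perm_a <- sample(n_probes); perm_i <- sample(n_icrs)
  got2 <- map_icrs(dmcs[perm_a, , drop = FALSE], ann[perm_a, ],
                   icrs[perm_i, ])$summary
  expect_equal(got2[c("n_dmcs", "n_icrs", "n_genes")],
               map_icrs(dmcs, ann, icrs)$summary[c("n_dmcs", "n_icrs", "n_genes")])

  # a probe inside two overlapping ICRs: one DMC count, two pairings
  ann2 <- data.frame(probe_id = "x", chr = "1", pos = 100)
  icrs2 <- data.frame(chr = "1", start = c(50, 90), end = c(150, 200),
                      gene = c("GA", "GB"),
                      origin = c("paternal", "paternal"))
  res2 <- map_icrs(data.frame(probe_id = "x"), ann2, icrs2)
  expect_equal(nrow(res2$hits), 2)
  expect_equal(res2$summary$n_dmcs[res2$summary$origin == "total"], 1)
})

test_that("gene matching explodes multi-gene annotations and uppercases", {
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    genes = c("GNAS;GNASAS", "gnas", "OTHER"),
                    stringsAsFactors = FALSE)
  imprinted <- data.frame(gene = "GNAS", status = "confirmed",
                          expressed_allele = "I", stringsAsFactors = FALSE)
  res <- map_genes(data.frame(probe_id = c("p1", "p2", "p3")), ann, imprinted)
  expect_equal(res$summary$n_genes_matched, 1)
  expect_equal(res$summary$n_dmcs_matched, 2)   # p1 and p2 both carry GNAS
  expect_equal(res$summary$n_genes_I, 1)

  empty <- map_genes(data.frame(probe_id = "p1"), ann,
                     imprinted[0, , drop = FALSE])
  expect_equal(nrow(empty$hits), 0)
  expect_equal(empty$summary$n_dmcs_matched, 0)
})

test_that("parent-of-origin summary reconciles alleles and flags multi-origin genes", {
  gene_hits <- data.frame(
    probe_id = sprintf("p%d", 1:6),
    gene = c("A", "A", "B", "C", "D", "E"),
    status = "confirmed",
    expressed_allele = c("M", "M", "M", "P", "P", "I"),
    stringsAsFactors = FALSE)
  icr_hits <- data.frame(
    probe_id = c("p1", "p2", "p3"),
    icr_id = 1:3,
    gene = c("A", "A", "B"),
    origin = c("paternal", "maternal", "unknown"),
    stringsAsFactors = FALSE)
  res <- parent_of_origin_summary(gene_hits, icr_hits)
  ba <- res$by_expressed_allele
  expect_equal(ba$n_genes[ba$expressed_allele == "M"], 2)
  expect_equal(ba$n_genes[ba$expressed_allele == "P"], 2)
  expect_equal(ba$n_genes[ba$expressed_allele == "I"], 1)
  expect_equal(ba$n_genes[ba$expressed_allele == "total"], 5)
  pairs <- attr(res$by_origin, "gene_origin_pairs")
  expect_true(all(pairs$multi_origin[pairs$gene == "A"]))
  expect_false(any(pairs$multi_origin[pairs$gene == "B"]))
  # gene A appears once per origin
  expect_equal(sum(pairs$gene == "A"), 2)
})

test_that("ICR BED files round-trip through read_icr_bed with conventions intact", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "icrs.bed")
  writeLines(c("1\t50\t150\tG1|paternal\t0\t.",
               "X\t0\t10\tG2|unknown\t0\t."), bed)
  icrs <- read_icr_bed(bed)
  expect_equal(icrs$start, c(50, 0))
  expect_equal(icrs$end, c(150, 10))
  expect_identical(icrs$origin, c("paternal", "unknown"))
  writeLines("1\t50\t150\tG1-paternal\t0\t.", bed)
  expect_error(read_icr_bed(bed), "gene\\|origin")
})
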