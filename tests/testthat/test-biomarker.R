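# Cross-study overlaps, indicator computation, score of interest, and the
# biomarker selection rule.

test_that("overlap_counts matches hand enumeration and Venn bookkeeping", {
  res <- overlap_counts(list(A = c("g1", "g2"), B = "g2", C = c("g2", "g3")))
  expect_equal(res$at_least$n_genes, c(3, 1, 1))  # >=1: all, >=2: g2, >=3: g2
  expect_true(all(diff(res$at_least$n_genes) <= 0))
  expect_equal(sum(res$venn$n_genes), 3)          # regions partition the union

  same <- overlap_counts(list(A = c("x", "y"), B = c("y", "x")))
  expect_equal(same$at_least$n_genes, c(2, 2))
  disjoint <- overlap_counts(list(A = "x", B = "y"))
  expect_equal(disjoint$at_least$n_genes[2], 0)
  expect_error(overlap_counts(list(A = "x")), "at least 2")
})

test_that("score_of_interest validates and sums the eight indicators", {
  expect_equal(score_of_interest(c(1, 0, 1, 1, 1, 0, 0, 1)), 5L)
  expect_equal(score_of_interest(c(1, 1, 1, 0, 0, 0, 1, 0)), 4L)
  expect_equal(score_of_interest(rep(0, 8)), 0L)
  expect_error(score_of_interest(c(1, 0, 2, 0, 0, 0, 0, 0)), "0 or 1")
  expect_error(score_of_interest(c(1, 0)), "8 elements")
})

test_that("the packaged score card reproduces every published score", {
  card <- load_example_scorecard()
  expect_equal(nrow(card), 28)
  scores <- score_of_interest(card)
  expect_equal(scores, card$score_printed)
  expect_equal(scores[card$gene == "MAGEL2"], 5L)
  expect_equal(scores[card$gene == "DLGAP2"], 4L)
  expect_equal(sum(card$icr == 1), 11)  # ICR-linked disease genes
})

test_that("indicators are evaluated per definition on a constructed gene set", {
  dmcs <- make_fit_table(
    probe_id = c("p1", "p2", "p3", "p4"),
    slope = c(0.12, -0.05, 0.05, -0.02),
    significant = TRUE,
    subgroup = c("UM", "FM", "HM", "HM"))
  ann <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    genes = c("GENEA", "GENEA", "GENEB", "GENEB;GENEC", "GENEC"),
    island_relation = c("Island", "OpenSea", "Shore", "OpenSea", "Island"),
    functional_region = c("promoter", "body", "body", "body", "promoter"),
    crossreactive = c(0, 0, 1, 0, 0),
    stringsAsFactors = FALSE)
  icr_hits <- data.frame(probe_id = "p2", icr_id = 1L, gene = "GENEA",
                         origin = "maternal", stringsAsFactors = FALSE)
  lists <- list(s1 = "GENEA", s2 = "GENEA", s3 = c("GENEA", "GENEB"))

  a <- compute_indicators("GENEA", dmcs, ann, icr_hits,
                          top_probes = "p1", external_lists = lists)
  # p1: +0.12 at UM site -> op and ma; p2 in an ICR; both probes -> multi
  expect_equal(unlist(a[c("icr", "co", "multi_cpg", "top90", "ma", "op",
                          "is_island", "pr")]),
               c(icr = 1, co = 1, multi_cpg = 1, top90 = 1, ma = 1, op = 1,
                 is_island = 1, pr = 1))
  expect_equal(a$score, 8L)
  expect_false(a$crossreactive_only)

  # single small-effect DMC: no magnitude, no multi-CpG flags
  b <- compute_indicators("GENEB", dmcs[3, ], ann, NULL,
                          external_lists = lists)
  expect_equal(b$ma, 0L)
  expect_equal(b$multi_cpg, 0L)
  expect_equal(b$co, 0L)        # in 1 list only, threshold is 3
  expect_true(b$crossreactive_only)  # its only DMC sits on a cr probe

  # positive slope at a UM site is "opposite direction" by itself
  c_ <- compute_indicators("GENEA", dmcs[1, , drop = FALSE], ann, NULL)
  expect_equal(c_$op, 1L)
  expect_error(compute_indicators("GENEZ", dmcs, ann), "no significant DMC")
})

test_that("select_biomarkers applies the ICR/score/pseudogene/cross-reactive rule", {
  card <- load_example_scorecard()
  card$score <- score_of_interest(card)
  asd <- card$gene                    # every gene in the card is ASD-related
  cr_only <- card$gene[card$crossreactive_probe == 1]
  sel <- select_biomarkers(card, asd_genes = asd,
                           pseudogenes = "SLC26A10",
                           crossreactive_only = cr_only)
  expect_equal(nrow(sel), 13)
  expect_true(all(c("MAGEL2", "DLGAP2", "OTX1", "PRDM16", "FBRSL1",
                    "KCNQ1", "KCNQ1OT1", "GNAS", "GRB10", "PTPRN2",
                    "PLAGL1", "B4GALNT4", "CDH24") %in% sel$gene))
  expect_false("SLC26A10" %in% sel$gene)   # pseudogene
  expect_false("C6orf145" %in% toupper(sel$gene))  # cross-reactive only
  expect_false("ATP10A" %in% sel$gene)     # score 2, no ICR

  # deterministic ordering and idempotence under row shuffles
  sel2 <- select_biomarkers(card[sample(nrow(card)), ], asd_genes = asd,
                            pseudogenes = "SLC26A10",
                            crossreactive_only = cr_only)
  expect_identical(sel$gene, sel2$gene)
  sel3 <- select_biomarkers(sel, asd_genes = asd, pseudogenes = "SLC26A10",
                            crossreactive_only = cr_only)
  expect_identical(sel3$gene, sel$gene)

  expect_equal(nrow(select_biomarkers(card, asd_genes = character())), 0)
  # an unreachable threshold keeps only the ICR-linked disease genes
  high <- select_biomarkers(card, asd_genes = asd, threshold = 9,
                            pseudogenes = "SLC26A10",
                            crossreactive_only = cr_only)
  expect_setequal(high$gene, card$gene[card$icr == 1])
})
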