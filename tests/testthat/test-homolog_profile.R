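test_that("filter_hits keeps e-values at or below the cutoff, in order", {
  h <- homolog_hits("FANCM", c("p1", "p2", "p3"), "t",
                    c(1e-6, 1e-5, 1e-4), c(300, 200, 100))
  f <- filter_hits(h, 1e-5)
  expect_equal(f$target_protein_id, c("p1", "p2"))  # cutoff is inclusive
  expect_equal(nrow(filter_hits(h[0, ], 1e-5)), 0)
  expect_identical(filter_hits(f, 1e-5), f)         # idempotent
  expect_lte(nrow(f), nrow(h))
})

test_that("filter_hits retains exactly the planted true homologs", {
  truth <- stats::setNames(fa_registry()$symbol,
                           paste0("prot_", fa_registry()$symbol))
  sim <- simulate_hit_table(truth, n_decoys = 60, seed = 4)
  f <- filter_hits(sim$hits, 1e-5)
  expect_setequal(unique(f$target_protein_id), names(truth))
})

test_that("assign_best picks the max-bitscore component deterministically", {
  h <- homolog_hits(c("FANCM", "FANCQ"), "P", "t", c(1e-20, 1e-10),
                    c(300, 120))
  expect_equal(assign_best(h)$component, "FANCM")
  one <- homolog_hits("SLX1", "P2", "t", 1e-8, 55)
  expect_equal(assign_best(one)$component, "SLX1")
  # full tie on bitscore and e-value: lexicographic symbol wins
  tie <- homolog_hits(c("FANCI", "FANCD2"), "P3", "t", c(1e-30, 1e-30),
                      c(200, 200))
  expect_equal(assign_best(tie)$component, "FANCD2")
  # permutation invariance with respect to hit order
  h2 <- rbind(h, one, tie)
  for (perm in list(c(5, 1, 3, 2, 4), 5:1)) {
    expect_identical(assign_best(h2[perm, ]), assign_best(h2))
  }
})

test_that("confirm_architecture gates on diagnostic domains", {
  asg <- assign_best(homolog_hits("FANCL", "pL", "t", 1e-40, 280))
  dom <- domain_annotations("pL", "PF11793", 5, 120)
  expect_equal(nrow(confirm_architecture(asg, dom)), 1)
  # wrong domain, gate on -> dropped with reason
  dom_bad <- domain_annotations("pL", "PF16783", 5, 120)
  expect_message(kept <- confirm_architecture(asg, dom_bad), "dropped")
  expect_equal(nrow(kept), 0)
  expect_match(attr(kept, "dropped")$reason, "PF11793")
  # gate off -> retained even with no domains
  expect_equal(nrow(confirm_architecture(asg, dom_bad, require = FALSE)), 1)
  # components without diagnostic accessions are exempt
  asg_rev3 <- assign_best(homolog_hits("REV3", "pR", "t", 1e-40, 280))
  expect_equal(nrow(confirm_architecture(asg_rev3, dom_bad[0, ])), 1)
  # unknown component symbol errors
  asg$component <- "NOT_A_COMPONENT"
  expect_error(confirm_architecture(asg, dom), "unknown component")
})

test_that("confirm_architecture drops exactly the planted wrong-domain set", {
  reg <- fa_registry()
  syms <- reg$symbol[nzchar(reg$pfam)][1:20]
  truth <- stats::setNames(syms, paste0("prot_", syms))
  sim <- simulate_hit_table(truth, seed = 8, n_wrong_domain = 5)
  asg <- assign_best(filter_hits(sim$hits))
  suppressMessages(kept <- confirm_architecture(asg, sim$domains))
  expect_equal(nrow(kept), 15)
  expect_setequal(attr(kept, "dropped")$protein_id, sim$wrong_domain_ids)
})

test_that("build_presence_matrix counts distinct proteins per cell", {
  asg <- data.frame(taxon_id = "A",
                    protein_id = c("P1", "P2", "P3"),
                    component = c("FANCM", "FANCM", "SLX1"),
                    stringsAsFactors = FALSE)
  mat <- build_presence_matrix(asg)
  expect_equal(mat["A", "FANCM"], 2L)
  expect_equal(mat["A", "SLX1"], 1L)
  expect_equal(sum(mat), 3L)
  # empty input -> all-zero matrix of requested shape
  z <- build_presence_matrix(asg[0, ], taxa = c("A", "B"))
  expect_equal(dim(z), c(2, 40))
  expect_true(all(z == 0))
})

test_that("presence matrix reconstructs planted copy numbers", {
  comps <- c("FANCJ", "FANCJ", "FANCM", "FANCL", "SLX1", "MUS81", "FAN1",
             "ATR", "UHRF1", "FANCD2", "FANCT")
  truth <- stats::setNames(comps, sprintf("taxA_p%02d", seq_along(comps)))
  sim <- simulate_hit_table(truth, n_decoys = 25, seed = 12,
                            taxon_id = "taxA")
  asg <- confirm_architecture(assign_best(filter_hits(sim$hits)),
                              sim$domains)
  mat <- build_presence_matrix(asg)
  expect_equal(sum(mat["taxA", ]), 11L)
  expect_equal(mat["taxA", "FANCJ"], 2L)
  expect_equal(mat["taxA", "FANCC"], 0L)
})

test_that("detect_fusions calls disjoint two-component architectures", {
  d <- domain_annotations("chytrid_p1", c("PF16783", "PF02732"),
                          c(10, 1500), c(200, 1700))
  calls <- detect_fusions(d)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$component_n, "FANCM")   # N-terminal helicase domain
  expect_equal(calls$component_c, "FANCQ")   # C-terminal XPF endonuclease
  # single-component proteins never fire
  expect_equal(nrow(detect_fusions(d[1, ])), 0)
  # overlapping intervals of two components' domains -> no call
  ov <- domain_annotations("p2", c("PF16783", "PF02732"),
                           c(10, 150), c(200, 400))
  expect_equal(nrow(detect_fusions(ov)), 0)
  # midpoints closer than min_separation -> no call
  near <- domain_annotations("p3", c("PF16783", "PF02732"),
                             c(10, 120), c(100, 180))
  expect_equal(nrow(detect_fusions(near, min_separation = 100)), 0)
  # a shared accession (PF08423: FANCO/FANCR/FANCU) cannot self-fuse
  shared <- domain_annotations("p4", "PF08423", 10, 150)
  expect_equal(nrow(detect_fusions(shared)), 0)
})

test_that("architecture_report lists truncations, acquisitions and length", {
  # FANCJ-like truncation: solo DEAD/DEAH box, no C-terminal RAD3 helicase
  trunc <- architecture_report(c("PF06733"), c("PF06733", "PF13307"),
                               protein_length = 450,
                               reference_length = 1200)
  expect_equal(trunc$missing, "PF13307")
  expect_equal(trunc$extra, character(0))
  expect_equal(trunc$length_ratio, 450 / 1200)
  # identical architectures
  same <- architecture_report(c("PF09494"), c("PF09494"))
  expect_equal(same$missing, character(0))
  expect_equal(same$extra, character(0))
  # SLX4-like acquisition of an extra N-terminal S2P-M50 domain
  extra <- architecture_report(c("S2P-M50", "SAP", "PF09494"),
                               c("SAP", "PF09494"))
  expect_equal(extra$extra, "S2P-M50")
  expect_error(architecture_report("PF1", character(0)), "non-empty")
})

test_that("hit tables round-trip through the outfmt-6 writer/reader", {
  truth <- stats::setNames(c("FANCM", "FANCT"), c("pA", "pB"))
  sim <- simulate_hit_table(truth, n_decoys = 3, seed = 2)
  path <- file.path(withr::local_tempdir(), "hits.tsv")
  write_hits(sim$hits, path)
  back <- read_hits(path)
  expect_equal(back$component, sim$hits$component)
  expect_equal(back$evalue, sim$hits$evalue, tolerance = 1e-12)
  # alias resolution: qseqid may use UBE2T/XPF style aliases
  h <- homolog_hits(c("UBE2T", "XPF"), c("x", "y"), "t", c(1e-9, 1e-9),
                    c(100, 100))
  expect_equal(h$component, c("FANCT", "FANCQ"))
})
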