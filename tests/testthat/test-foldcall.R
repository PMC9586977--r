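# the reference fold's zf-C3HC module layout, as a synthetic sequence:
# R89 xx S92, G118-W119, C134/C137/H172/C176, W178
ref_zf_sequence <- function() {
  planted_sequence(200, c(89, 92, 118, 119, 134, 137, 172, 176, 178),
                   c("R", "S", "G", "W", "C", "C", "H", "C", "W"))
}

test_that("anchors are located around a reference-style zinc finger", {
  s <- ref_zf_sequence()
  m <- scan_znf(s, znf_grammar("zf_C3HC"))
  expect_equal(nrow(m), 1)
  a <- find_anchors(s, m)
  expect_equal(a$r_pos, 89L)
  expect_equal(a$st_pos, 92L)
  expect_equal(a$g_pos, 118L)
  expect_equal(a$omega_g_pos, 119L)
  expect_equal(a$final_omega_pos, 178L)
})

test_that("the Rxx(S/T) motif is found even without the +4 aromatic", {
  # Rsm1-style placement: Arg and Thr only
  s <- planted_sequence(310, c(202, 205, 256, 257, 268, 271, 288, 292, 294),
                        c("R", "T", "G", "Y", "C", "C", "H", "C", "Y"))
  m <- scan_znf(s, znf_grammar("Rsm1"))
  a <- find_anchors(s, m[1, ])
  expect_equal(a$r_pos, 202L)
  expect_equal(a$st_pos, 205L)
  expect_true(is.na(a$omega_a_pos))
})

test_that("absent anchors are reported as absent, not as errors", {
  s <- planted_sequence(60, c(10, 13, 48, 52), c("C", "C", "H", "C"))
  a <- find_anchors(s, scan_znf(s, znf_grammar("zf_C3HC")))
  expect_true(is.na(a$r_pos))
  expect_true(is.na(a$g_pos))
  expect_true(is.na(a$final_omega_pos))
})

test_that("module classification follows spacer and insertion rules", {
  # H-C spacer 6 is canonical BIR regardless of anchors
  s6 <- planted_sequence(80, c(10, 13, 48, 55), c("C", "C", "H", "C"))
  m6 <- scan_znf(s6, znf_grammar("canonical_BIR"))
  expect_equal(classify_module(s6, m6)$kind, "canonical_BIR")

  # arginine-to-glycine distance 29 (89 -> 118): zf-C3HC
  s <- ref_zf_sequence()
  cm <- classify_module(s, scan_znf(s, znf_grammar("zf_C3HC")))
  expect_equal(cm$kind, "zf_C3HC")
  expect_equal(cm$score, 1)

  # distance 54 (202 -> 256): the inter-anchor insertion marks Rsm1
  sr <- planted_sequence(310, c(202, 205, 256, 257, 268, 271, 288, 292, 294),
                         c("R", "T", "G", "Y", "C", "C", "H", "C", "Y"))
  cr <- classify_module(sr, scan_znf(sr, znf_grammar("Rsm1")))
  expect_equal(cr$kind, "Rsm1")
  expect_equal(cr$score, 1)
})

test_that("classification is deterministic and ignores residues outside the span", {
  gen <- sim_module_sequence(11, "zf_C3HC")
  m <- scan_znf(gen$sequence, znf_grammar("zf_C3HC"))
  base <- classify_module(gen$sequence, m)
  # mutate residues outside the module span (background letters only)
  chars <- strsplit(gen$sequence, "")[[1]]
  outside <- setdiff(seq_along(chars),
                     seq(base$span_start, base$span_end))
  chars[outside] <- "A"
  mutated <- paste(chars, collapse = "")
  again <- classify_module(mutated, scan_znf(mutated, znf_grammar("zf_C3HC")))
  expect_equal(again, base)
  expect_equal(classify_module(gen$sequence, m), base)  # deterministic
})

test_that("a grammar-violating match is rejected", {
  s <- ref_zf_sequence()
  m <- scan_znf(s, znf_grammar("zf_C3HC"))
  bad <- m; bad$c1 <- 90L  # not a cysteine
  expect_error(classify_module(s, bad), "CCHC")
})

test_that("tandem fold calls require both modules in N-to-C order", {
  ts <- sim_tandem_sequence(21)
  call <- detect_pml39_fold("tandem", annotate_modules(ts$sequence))
  expect_true(call$is_pml39_fold)
  expect_equal(call$satisfied_count, 18L)
  expect_lt(call$zf_end, call$rsm1_start)

  single <- sim_module_sequence(22, "zf_C3HC")
  call1 <- detect_pml39_fold("single", annotate_modules(single$sequence))
  expect_false(call1$is_pml39_fold)

  rev <- sim_tandem_sequence(23, order = "rsm1_zf")
  call_rev <- detect_pml39_fold("reversed", annotate_modules(rev$sequence))
  expect_false(call_rev$is_pml39_fold)
})

test_that("reference residue maps meet all 18 checklist criteria", {
  for (map in list(scpml39_residue_map(), sprsm1_residue_map(),
                   hsnipa_residue_map())) {
    rep <- ortholog_checklist(map)
    expect_equal(rep$satisfied_count, 18L)
    expect_equal(rep$total, 18L)
  }
})

test_that("single-residue knockouts cost exactly the affected criterion", {
  map <- scpml39_residue_map()
  # remove the final aromatic of the second module
  ko <- map[!(map$module == "Rsm1" & map$role == "OmegaF"), ]
  expect_equal(ortholog_checklist(ko)$satisfied_count, 17L)
  # substituting it with a non-aromatic has the same effect
  sub <- map
  sub$residue[sub$module == "Rsm1" & sub$role == "OmegaF"] <- "A"
  expect_equal(ortholog_checklist(sub)$satisfied_count, 17L)
  # X never satisfies a criterion
  xmap <- map
  xmap$residue[xmap$module == "zf_C3HC" & xmap$role == "C1"] <- "X"
  expect_equal(ortholog_checklist(xmap)$satisfied_count, 17L)
})

test_that("checklist score is monotone under removal of map entries", {
  map <- scpml39_residue_map()
  withr::with_seed(7, {
    for (i in 1:10) {
      drop_n <- sample(nrow(map) - 1, 1)
      sub <- map[-sample(nrow(map), drop_n), ]
      expect_lte(ortholog_checklist(sub)$satisfied_count, 18L)
      # removing further entries never increases the count
      sub2 <- sub[-sample(nrow(sub), 1), ]
      expect_lte(ortholog_checklist(sub2)$satisfied_count,
                 ortholog_checklist(sub)$satisfied_count)
    }
  })
})

test_that("duplicate criterion keys are rejected", {
  map <- rbind(scpml39_residue_map(), scpml39_residue_map()[1, ])
  expect_error(ortholog_checklist(map), "duplicate")
})

test_that("planted motifs are recovered exactly, and only under their grammar", {
  for (seed in 1:8) {
    fam <- c("zf_C3HC", "Rsm1")[(seed %% 2) + 1]
    gen <- sim_module_sequence(seed, fam)
    m <- scan_znf(gen$sequence, znf_grammar(fam))
    expect_equal(nrow(m), 1)
    expect_equal(unlist(m[1, c("c1", "c2", "h", "c3")], use.names = FALSE),
                 unlist(gen$truth[, c("c1", "c2", "h", "c3")], use.names = FALSE))
    expect_equal(nrow(scan_znf(gen$sequence, znf_grammar("canonical_BIR"))), 0)
    ann <- annotate_modules(gen$sequence)
    expect_equal(ann$kind, fam)
  }
})
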