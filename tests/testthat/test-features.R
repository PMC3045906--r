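test_that("residue composition is a frequency vector on the simplex", {
  comp <- residue_composition("ACDG")
  expect_equal(unname(comp[c("A", "C", "D", "G")]), rep(0.25, 4))
  expect_equal(sum(comp), 1)
  expect_equal(unname(residue_composition("AAAA")["A"]), 1)
  comp20 <- residue_composition(paste(AA_ALPHABET, collapse = ""))
  expect_equal(unname(comp20), rep(0.05, 20))
  expect_error(residue_composition(""), "empty")
  expect_error(residue_composition("MKX"), "non-canonical")
  # simplex property on random sequences
  set.seed(1)
  for (i in 1:25)
    expect_equal(sum(residue_composition(random_aa_sequence(sample(1:200, 1)))), 1)
})

test_that("index means are composition-weighted averages", {
  expect_equal(index_mean("AC", c(A = 1, C = 2)), 1.5)
  const <- stats::setNames(rep(3.7, 20), AA_ALPHABET)
  expect_equal(index_mean(random_aa_sequence(50), const), 3.7)
  # Hopp-Woods hydrophilicity: Asp is hydrophilic, Phe hydrophobic
  tab <- default_aaindex_table()
  hw <- unclass(tab)["HOPT810101", ]
  expect_gt(hw[["D"]], hw[["F"]])
  expect_gt(index_mean("DDDD", hw), index_mean("FFFF", hw))
})

test_that("index means are linear in sequence concatenation", {
  tab <- default_aaindex_table()
  v <- unclass(tab)["KYTJ820101", ]
  set.seed(2)
  for (i in 1:10) {
    s1 <- random_aa_sequence(sample(10:80, 1))
    s2 <- random_aa_sequence(sample(10:80, 1))
    n1 <- nchar(s1); n2 <- nchar(s2)
    expect_equal(index_mean(paste0(s1, s2), v),
                 (n1 * index_mean(s1, v) + n2 * index_mean(s2, v)) / (n1 + n2))
  }
})

test_that("isoelectric point matches the dense grid-scan oracle", {
  # termini only: charge-zero midpoint of the two terminal pKa values
  expect_equal(isoelectric_point("GGGGG"), (8.6 + 3.6) / 2, tolerance = 2e-3)
  expect_equal(isoelectric_point("GGGGG"), oracle_grid_pi("GGGGG"),
               tolerance = 2e-3)
  # acidic residues lower the pI, basic residues raise it
  expect_lt(isoelectric_point("DDDD"), isoelectric_point("GGGG"))
  expect_lt(isoelectric_point("GGGG"), isoelectric_point("KKKK"))
  set.seed(3)
  for (i in 1:60) {
    s <- random_aa_sequence(sample(5:120, 1))
    expect_equal(isoelectric_point(s), oracle_grid_pi(s), tolerance = 2e-3)
  }
})

test_that("appending an acidic residue never raises the pI", {
  set.seed(4)
  for (i in 1:100) {
    s <- random_aa_sequence(sample(5:80, 1))
    expect_lte(isoelectric_point(paste0(s, "D")),
               isoelectric_point(s) + 2e-3)
  }
})

test_that("the eight frequency ratios follow their definitions", {
  gly <- residue_composition("GGGG")
  r <- ratio_features(gly, length = 4)
  expect_equal(unname(r["r_charged_all"]), 0)
  expect_equal(unname(r["r_neg_pos"]), 0)  # zero numerator beats pseudocount
  dekr <- residue_composition("DEKR")
  r2 <- ratio_features(dekr, length = 4)
  expect_equal(unname(r2["r_charged_all"]), 1)
  expect_equal(unname(r2["r_neg_pos"]), 1)
  ddek <- residue_composition("DDEK")
  expect_equal(unname(ratio_features(ddek, length = 4)["r_neg_pos"]), 3)
})

test_that("per-protein feature vectors have the full-set schema", {
  tab <- default_aaindex_table()
  codes <- feature_codes(tab)
  expect_length(codes, 79)
  fv <- protein_features("MKVDDE", tab)
  expect_identical(names(fv), codes)
  fv2 <- protein_features("AAAA", tab)
  expect_equal(unname(fv2["protein_length"]), 4)
  expect_equal(unname(fv2["comp_A"]), 1)
  dc <- attr(fv, "derived_charges")
  expect_equal(unname(dc["negative_charge"]), 3 / 6)
  expect_equal(unname(dc["positive_charge"]), 1 / 6)
  expect_equal(unname(dc["charge"]), 4 / 6)
})

test_that("all descriptors are order-independent", {
  tab <- default_aaindex_table()
  set.seed(5)
  s <- random_aa_sequence(80)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(protein_features(s, tab), protein_features(perm, tab),
               ignore_attr = TRUE)
})

test_that("proteome features are unweighted means over proteins", {
  tab <- default_aaindex_table()
  one <- proteome_record("one", "MKVDDE")
  expect_equal(proteome_features(one, tab), protein_features("MKVDDE", tab),
               ignore_attr = TRUE)
  two <- proteome_record("two", c(random_aa_sequence(100),
                                  random_aa_sequence(300)))
  expect_equal(unname(proteome_features(two, tab)["protein_length"]), 200)
  # mean of per-protein compositions, NOT the pooled-residue frequency:
  # proteins AAAA (4 A) and CC (2 C) -> mean f(A) = (1+0)/2 = 0.5,
  # while pooling residues would give 4/6
  contrast <- proteome_record("c", c("AAAA", "CC"))
  pf <- proteome_features(contrast, tab)
  expect_equal(unname(pf["comp_A"]), 0.5)
  expect_equal(unname(pf["comp_C"]), 0.5)
  expect_false(isTRUE(all.equal(unname(pf["comp_A"]), 4 / 6)))
})

test_that("feature matrices are complete and recover planted directions", {
  sh <- shared_halo_data()
  fm <- sh$features
  expect_identical(dim(fm), c(16L, 79L))
  expect_false(anyNA(fm))
  comp_cols <- paste0("comp_", AA_ALPHABET)
  expect_equal(unname(rowSums(fm[, comp_cols])), rep(1, nrow(fm)),
               tolerance = 1e-9)
  labels <- sh$labels$labels
  acidic <- fm[sh$labels$organism_ids, "comp_D"] +
    fm[sh$labels$organism_ids, "comp_E"]
  expect_gt(mean(acidic[labels == "halophile"]),
            mean(acidic[labels == "non-halophile"]))
})

test_that("feature matrix TSV round-trips", {
  sh <- shared_halo_data()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(sh$features, f)
  back <- read_feature_matrix(f)
  expect_identical(colnames(back), colnames(sh$features))
  expect_equal(back, sh$features, tolerance = 1e-10)
})

test_that("a custom index table TSV round-trips and drives extraction", {
  vals <- matrix(seq_len(40), nrow = 2, byrow = TRUE,
                 dimnames = list(c("IDX1", "IDX2"), AA_ALPHABET))
  tab <- aaindex_table(vals, c("first toy scale", "second toy scale"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_aaindex_table(tab, f)
  back <- read_aaindex_table(f)
  expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
  fv <- protein_features("AC", back)
  expect_length(fv, 20 + 2 + 2 + 8 + 1)
  expect_equal(unname(fv["IDX1"]), (1 + 2) / 2)
})
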