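test_that("amino-acid composition is a normalized count vector", {
  v <- aa_composition("AAAA")
  expect_equal(unname(v["AAC_A"]), 1)
  expect_equal(sum(v), 1)
  v2 <- aa_composition("ACAC")
  expect_equal(unname(v2[c("AAC_A", "AAC_C")]), c(0.5, 0.5))
  withr::with_seed(5, {
    for (n in c(1, 7, 113)) {
      expect_equal(sum(aa_composition(random_sequence(n))), 1)
    }
  })
  expect_error(aa_composition(""), "position|composition|Empty")
})

test_that("dipeptide composition follows the overlapping-count definition", {
  v <- dipeptide_composition("AAA")
  expect_length(v, 400L)
  expect_equal(unname(v["DPC_AA"]), 1)
  expect_equal(sum(v != 0), 1L)

  v2 <- dipeptide_composition("ACA")
  expect_equal(unname(v2[c("DPC_AC", "DPC_CA")]), c(0.5, 0.5))

  expect_error(dipeptide_composition("A"), "no dipeptides")
})

test_that("dipeptide composition sums to 1 with components in [0,1]", {
  withr::with_seed(17, {
    for (n in c(2, 3, 25, 400)) {
      v <- dipeptide_composition(random_sequence(n))
      expect_length(v, 400L)
      expect_equal(sum(v), 1, tolerance = 1e-12)
      expect_true(all(v >= 0 & v <= 1))
    }
  })
})

test_that("dipeptide composition is orientation-sensitive but exact", {
  expect_equal(unname(dipeptide_composition("AC")["DPC_AC"]), 1)
  expect_equal(unname(dipeptide_composition("CA")["DPC_CA"]), 1)
  # alternating sequence of length 2k: DPC_AC = k/(2k-1), exactly
  for (k in c(2, 5, 31)) {
    s <- strrep("AC", k)
    expect_identical(unname(dipeptide_composition(s)["DPC_AC"]),
                     k / (2 * k - 1))
  }
})

test_that("Moran autocorrelation matches the brute-force oracle", {
  scale <- property_scale("Mutability", standardize = TRUE)
  expect_equal(moran_autocorrelation("AAAAA", scale, 1), 0)

  two <- setNames(c(1, -1, rep(0, 18)), c("A", "C", setdiff(AA20, c("A", "C"))))
  expect_equal(moran_autocorrelation("ACACAC", two, 2),
               oracle_moran("ACACAC", two, 2), tolerance = 1e-12)

  withr::with_seed(23, {
    s <- random_sequence(40)
    sc <- setNames(rnorm(20), AA20)
    for (d in 1:30) {
      got <- moran_autocorrelation(s, sc, d)
      want <- oracle_moran(s, sc, d)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
  expect_error(moran_autocorrelation("ACDE", scale, 4), "outside")
})

test_that("Moran is affine-invariant in the scale and reversal-symmetric", {
  withr::with_seed(29, {
    for (rep in 1:5) {
      s <- random_sequence(60)
      sc <- setNames(rnorm(20), AA20)
      d <- sample(1:20, 1)
      expect_equal(moran_autocorrelation(s, 3.7 * sc + 11, d),
                   moran_autocorrelation(s, sc, d), tolerance = 1e-10)
      rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
      expect_equal(moran_autocorrelation(rev_s, sc, d),
                   moran_autocorrelation(s, sc, d), tolerance = 1e-12)
    }
  })
})

test_that("Moran profile has the documented names and excludes short inputs", {
  cfg <- descriptor_config(families = "MoranAuto",
                           moran_scales = c("Mutability", "Steric"),
                           moran_max_lag = 30)
  withr::with_seed(31, s <- random_sequence(80))
  prof <- moran_profile(s, cfg)
  expect_length(prof, 60L)
  expect_true("MoranAuto_Mutability27" %in% names(prof))
  expect_equal(unname(moran_profile(strrep("A", 40), cfg)), rep(0, 60))
  expect_error(moran_profile(random_sequence(20), cfg), "exceed")
})

test_that("PAAC matches the literal-formula oracle and normalizes to 1", {
  withr::with_seed(37, s <- random_sequence(30))
  cfg <- descriptor_config(paac_lambda = 5, paac_weight = 0.05)
  got <- paac(s, cfg)
  expect_equal(unname(got), oracle_paac(s, 5, 0.05), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_true(all(got >= 0))

  # lambda = 0 reduces exactly to the amino-acid composition
  cfg0 <- descriptor_config(paac_lambda = 0)
  expect_equal(unname(paac(s, cfg0)), unname(aa_composition(s)))
  expect_error(paac(random_sequence(5), cfg), "lambda")
})

test_that("APAAC matches the literal-formula oracle", {
  withr::with_seed(41, s <- random_sequence(30))
  cfg <- descriptor_config(paac_lambda = 5, paac_weight = 0.05)
  got <- apaac(s, cfg)
  expect_equal(unname(got), oracle_apaac(s, 5, 0.05), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_length(apaac(s, descriptor_config(paac_lambda = 10)), 40L)
  cfg0 <- descriptor_config(paac_lambda = 0)
  expect_equal(unname(apaac(s, cfg0)), unname(aa_composition(s)))
})

test_that("CTD matches the per-definition oracle on all properties", {
  withr::with_seed(43, s <- random_sequence(20))
  got <- ctd(s)
  expect_length(got, 147L)
  for (prop in names(ppiselect:::CTD_PROPERTIES)) {
    idx <- grep(paste0("^CTD_", prop, "_"), names(got))
    want <- oracle_ctd_property(s, ppiselect:::CTD_PROPERTIES[[prop]])
    expect_equal(unname(got[idx]), want, tolerance = 1e-12)
  }
})

test_that("CTD composition partitions and degenerate classes behave", {
  # all residues buried w.r.t. solvent accessibility
  v <- ctd("ALFCGIVWALFCGIVW")
  expect_equal(unname(v["CTD_SolventAccessibility_C_1"]), 1)
  expect_equal(unname(v[c("CTD_SolventAccessibility_C_2",
                          "CTD_SolventAccessibility_C_3")]), c(0, 0))
  expect_equal(unname(v[grep("SolventAccessibility_T", names(v))]),
               rep(0, 3))
  withr::with_seed(47, s <- random_sequence(90))
  v2 <- ctd(s)
  for (prop in names(ppiselect:::CTD_PROPERTIES)) {
    expect_equal(sum(v2[paste0("CTD_", prop, "_C_", 1:3)]), 1,
                 tolerance = 1e-12)
  }
  expect_error(ctd("A"), "N >= 2")
})

test_that("full descriptor vectors share a schema across proteins", {
  cfg <- descriptor_config(families = c("AAC", "DPC"))
  v <- descriptor_vector("ACDEFGHIKLMNPQRSTVWY", cfg)
  expect_length(v, 420L)
  v2 <- descriptor_vector(strrep("MKV", 10), cfg)
  expect_identical(names(v), names(v2))

  dpc_only <- descriptor_vector("AAA", descriptor_config(families = "DPC"))
  expect_equal(sum(dpc_only != 0), 1L)
  expect_equal(unname(dpc_only["DPC_AA"]), 1)
})

test_that("compute_descriptors excludes too-short proteins with a reason", {
  recs <- tibble::tibble(
    id = c("long1", "long2", "short"),
    sequence = c(random_sequence(80), random_sequence(90),
                 random_sequence(12)))
  cfg <- descriptor_config(families = c("DPC", "MoranAuto"),
                           moran_max_lag = 30)
  feats <- suppressMessages(compute_descriptors(recs, cfg))
  expect_equal(feats$id, c("long1", "long2"))
  expect_named(attr(feats, "excluded"), "short")
  expect_equal(ncol(feats), 1L + 400L + 60L)
  schema <- descriptor_schema(feats)
  expect_equal(schema$n_features, 460L)
})

test_that("property scales are complete and standardization is affine", {
  for (nm in list_property_scales()) {
    sc <- property_scale(nm)
    expect_length(sc, 20L)
    expect_true(all(is.finite(sc)))
  }
  std <- property_scale("Steric", standardize = TRUE)
  expect_equal(mean(std), 0, tolerance = 1e-12)
  expect_equal(sd(std), 1, tolerance = 1e-12)
})
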