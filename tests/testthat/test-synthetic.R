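test_that("all generators are bit-reproducible under a fixed seed", {
  spec <- synth_spec(seed = 77, n_residues = 12L)
  expect_identical(gen_cpmg_table(spec, "0402"),
                   gen_cpmg_table(spec, "0402"))
  expect_identical(gen_hdx_tables(spec), gen_hdx_tables(spec))
  expect_identical(gen_pfg_table(spec), gen_pfg_table(spec))
  expect_identical(gen_elisa_plate(spec), gen_elisa_plate(spec))
  t1 <- gen_toy_ensemble(spec)
  t2 <- gen_toy_ensemble(spec)
  expect_identical(t1$ensemble$coords, t2$ensemble$coords)
  # a different seed changes the data
  spec2 <- synth_spec(seed = 78, n_residues = 12L)
  expect_false(identical(gen_cpmg_table(spec2, "0402"),
                         gen_cpmg_table(spec, "0402")))
})

test_that("the study writer emits every table plus ground-truth sidecars", {
  spec <- synth_spec(seed = 5, n_residues = 15L)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_study(spec, dir)
  for (iso in c("0401", "0402", "0403", "0404")) {
    expect_true(file.exists(file.path(dir, sprintf("cpmg_%s.tsv", iso))))
    expect_true(file.exists(file.path(dir, "truth",
                                      sprintf("cpmg_%s.tsv", iso))))
  }
  for (f in c("hdx_ref.tsv", "hdx_test.tsv", "pfg.tsv", "elisa_plate.csv",
              "ensemble.pdb")) {
    expect_true(file.exists(file.path(dir, f)))
  }
  # the written tables parse back through the readers
  rec <- read_cpmg_table(file.path(dir, "cpmg_0401.tsv"))
  expect_equal(sort(unique(rec$nu_cpmg_hz)),
               sort(unique(cpmg_nu_grid(TRUE))))
  expect_equal(length(unique(rec$residue)), 15)
  hdx <- read_hdx_table(file.path(dir, "hdx_ref.tsv"))
  expect_true(all(diff(hdx$time_s[hdx$residue == 1]) > 0))
  plate <- read_elisa_plate(file.path(dir, "elisa_plate.csv"))
  expect_equal(sum(plate$content == "standard"), 21)
  e <- read_pdb_ensemble(file.path(dir, "ensemble.pdb"))
  expect_equal(e$n_models, spec$ensemble$n_models)
})

test_that("CPMG generation respects the flexible fraction and amp window", {
  spec <- synth_spec(seed = 6)
  g <- gen_cpmg_table(spec, "0401")
  expect_equal(sum(g$truth$flexible), round(0.33 * 160))
  amps <- g$truth$delta_r2eff[g$truth$flexible]
  expect_true(all(amps >= spec$cpmg$amp_window[1] &
                    amps <= spec$cpmg$amp_window[2]))
  expect_true(all(g$truth$delta_r2eff[!g$truth$flexible] == 0))
  # zero flexible fraction gives flat profiles only
  spec0 <- synth_spec(seed = 6, n_residues = 20L,
                      cpmg = list(fractions = c("0401" = 0)))
  g0 <- gen_cpmg_table(spec0, "0401")
  expect_true(all(!g0$truth$flexible))
})

test_that("ELISA generation hits its target medians and rank structure", {
  spec <- synth_spec(seed = 30)
  e <- gen_elisa_plate(spec)
  v <- e$truth_matrix
  expect_equal(apply(v, 2, median),
               c("0401" = 2.02, "0402" = 1.21, "0403" = 1.57,
                 "0404" = 0.88))
  # dominant within-patient ordering in exactly 91% of patients
  follows <- apply(v, 1, function(x) {
    all(x["0401"] > x["0403"], x["0403"] > x["0402"],
        x["0402"] > x["0404"])
  })
  expect_equal(sum(follows), 20)
  # the two exceptions put 0403 on top
  expect_true(all(v[!follows, "0403"] > v[!follows, "0401"]))
})

test_that("HDX generation accelerates exactly the designated residues", {
  spec <- synth_spec(seed = 31)
  h <- gen_hdx_tables(spec)
  expect_equal(h$truth$residue[h$truth$accelerated],
               c(9L, 101L, 107L, 154L))
  expect_equal(h$truth$rate_test[h$truth$accelerated] /
                 h$truth$rate_ref[h$truth$accelerated], rep(5, 4))
  off <- !h$truth$accelerated
  expect_equal(h$truth$rate_test[off], h$truth$rate_ref[off])
  # acceleration factor 1 yields an empty accelerated set
  spec1 <- synth_spec(seed = 31, n_residues = 30L, hdx = list(factor = 1))
  h1 <- gen_hdx_tables(spec1)
  f1r <- fit_hdx_table(h1$ref)
  f1t <- fit_hdx_table(h1$test)
  expect_length(accelerated_residue_set(f1r, f1t, 4), 0)
})
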