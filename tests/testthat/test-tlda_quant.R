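make_ct <- function(rows, ref = "GAPDH", cal = "calibrator") {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], gene = r[[2]],
               replicate = as.integer(r[[3]]),
               ct = suppressWarnings(as.numeric(r[[4]])),
               undetermined = is.na(suppressWarnings(as.numeric(r[[4]]))),
               stringsAsFactors = FALSE)
  }))
  structure(df, reference_gene = ref, calibrator_id = cal,
            class = c("ct_table", "data.frame"))
}

test_that("ddCt closed forms: RQ = 2^-ddCt with calibrator at 1", {
  ct <- make_ct(list(
    list("s1", "tg", 1, 25), list("s1", "GAPDH", 1, 20),
    list("calibrator", "tg", 1, 27), list("calibrator", "GAPDH", 1, 20)))
  rq <- compute_rq(ct)
  expect_equal(rq$ddct["tg", "s1"], -2)
  expect_equal(rq$rq["tg", "s1"], 4)
  expect_equal(unname(rq$rq_full["tg", "calibrator"]), 1)

  # sample identical to the calibrator: RQ = 1
  ct2 <- make_ct(list(
    list("s1", "tg", 1, 27), list("s1", "GAPDH", 1, 20),
    list("calibrator", "tg", 1, 27), list("calibrator", "GAPDH", 1, 20)))
  expect_equal(compute_rq(ct2)$rq["tg", "s1"], 1)
})

test_that("replicates average; their SD is reported", {
  ct <- make_ct(list(
    list("s1", "tg", 1, 24.9), list("s1", "tg", 2, 25.1),
    list("s1", "GAPDH", 1, 20), list("s1", "GAPDH", 2, 20),
    list("calibrator", "tg", 1, 25), list("calibrator", "GAPDH", 1, 20)))
  rq <- compute_rq(ct)
  expect_equal(rq$ddct["tg", "s1"], 0)        # mean 25.0 used
  expect_equal(rq$ct_sd["tg", "s1"], 0.1414, tolerance = 1e-3)
  expect_equal(rq$n_rep["tg", "s1"], 2)
})

test_that("undetermined wells degrade gracefully, never imputed", {
  ct <- make_ct(list(
    list("s1", "tg", 1, NA), list("s1", "tg", 2, 24),
    list("s1", "GAPDH", 1, 20),
    list("s2", "tg", 1, NA), list("s2", "tg", 2, NA),
    list("s2", "GAPDH", 1, 20),
    list("calibrator", "tg", 1, 25), list("calibrator", "GAPDH", 1, 20)))
  rq <- compute_rq(ct)
  expect_equal(rq$ddct["tg", "s1"], -1)       # surviving replicate used
  expect_equal(rq$n_rep["tg", "s1"], 1)
  expect_true(is.na(rq$rq["tg", "s2"]))
  expect_equal(nrow(rq$missing_wells), 1L)
})

test_that("log2(RQ) = -ddCt exactly; constant Ct shifts cancel", {
  cfg <- simulation_config(n_genes = 40, n_controls = 0, n_de = 4, delta = 1,
                           sigma_gene = 0.2, ct_noise_sd = 0.2, seed = 12)
  coh <- generate_cohort(cfg)
  genes <- coh$truth$de_genes$gene
  ct <- generate_ct_table(coh$expr_true, genes, cfg)
  rq <- compute_rq(ct)
  expect_equal(log2(rq$rq), -rq$ddct, tolerance = 1e-12)

  shifted <- ct
  shifted$ct[shifted$sample_id == "P001"] <-
    shifted$ct[shifted$sample_id == "P001"] + 3.7
  rq2 <- compute_rq(shifted)
  expect_equal(rq2$rq[, "P001"], rq$rq[, "P001"], tolerance = 1e-10)
})

test_that("replicate noise does not bias mean ddCt", {
  M <- matrix(0.8, 1, 20, dimnames = list("g", sprintf("s%02d", 1:20)))
  means <- sapply(c(0.1, 0.2), function(noise) {
    vals <- sapply(1:8, function(seed) {
      cfg <- simulation_config(ct_noise_sd = noise, seed = seed)
      mean(compute_rq(generate_ct_table(M, "g", cfg))$ddct)
    })
    mean(vals)
  })
  # truth: ddCt = -M = -0.8; doubling the noise leaves the mean unbiased
  expect_equal(means[1], -0.8, tolerance = 0.05)
  expect_equal(means[2], -0.8, tolerance = 0.1)
  expect_equal(means[1], means[2], tolerance = 0.1)
})

test_that("qRT-PCR fold changes follow the signed NR/R convention", {
  rqm <- structure(list(rq = rbind(
    up = c(rep(6.04, 3), rep(1, 3)),
    flat = rep(1, 6),
    down = c(rep(0.3096, 3), rep(1, 3)))), class = "rq_matrix")
  colnames(rqm$rq) <- sprintf("s%d", 1:6)
  sheet <- structure(data.frame(patient_id = colnames(rqm$rq),
                                response = rep(c("NR", "CCR"), each = 3),
                                regimen = "PF"),
                     class = c("sample_sheet", "data.frame"))
  fc <- suppressWarnings(tlda_fold_change(rqm, sheet))  # zero-variance p warns
  expect_equal(round(fc$fc_signed[fc$gene == "up"], 2), 6.04)
  expect_equal(fc$fc_signed[fc$gene == "flat"], 1)
  expect_equal(round(fc$fc_signed[fc$gene == "down"], 2), -3.23)
})

test_that("signature transfer keeps the gene set and refits on RQ scale", {
  cfg <- simulation_config(n_genes = 300, n_controls = 15, n_de = 8,
                           delta = 2, sigma_gene = 0.2, ct_noise_sd = 0.1,
                           seed = 14)
  coh <- generate_cohort(cfg)
  expr <- preprocess_arrays(coh$arrays, coh$sheet)
  cvr <- loocv_with_reselection(expr, coh$sheet)
  model <- derive_final_signature(cvr, expr, coh$sheet,
                                  k = min(8, length(cvr$selection_frequency)))
  ct <- generate_ct_table(coh$expr_true, model$genes, cfg)
  rq <- compute_rq(ct)
  tr <- transfer_signature(model, rq, coh$sheet, retrain = TRUE)
  expect_equal(sort(tr$model$genes), sort(model$genes))
  expect_lte(abs(tr$cv$accuracy - cvr$accuracy), 0.1)

  # frozen model classifies new responder-like samples as CCR
  new_M <- matrix(0, length(model$genes), 5,
                  dimnames = list(model$genes, sprintf("new%d", 1:5)))
  ct_new <- generate_ct_table(new_M, model$genes, cfg)
  rq_new <- compute_rq(ct_new)
  frozen <- transfer_signature(tr$model, rq_new, retrain = FALSE)
  expect_gte(sum(frozen$predictions$predicted == "CCR"), 4)

  # contract errors
  bad_rq <- rq
  bad_rq$rq <- rq$rq[setdiff(rownames(rq$rq), model$genes[1]), , drop = FALSE]
  err <- expect_error(transfer_signature(model, bad_rq, coh$sheet),
                      class = "chemosig_key_error")
  expect_match(conditionMessage(err), model$genes[1], fixed = TRUE)
  expect_error(transfer_signature(model, rq_new, retrain = FALSE),
               class = "chemosig_state_error")
})
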