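noise_free <- function(...) optical_params(noise_model = list(type = "none"),
                                           ...)

test_that("crosstalk-free channels give the plain FRET/donor ratio", {
  tr <- data.frame(cell_id = "c", cycle = 1:2, donor = 100, fret = 200,
                   acceptor = 50, bg_donor = 0, bg_fret = 0,
                   bg_acceptor = 0)
  rt <- correct_ratio(tr, bleedthrough(0, 0, 0))
  expect_equal(rt$ratio, c(2, 2))
})

test_that("correction inverts the forward composition exactly", {
  # D = 100, A = 50, S = 150, bt = (0.57, 0.26, 0.02), bg = 10
  bt <- bleedthrough(0.57, 0.26, 0.02)
  donor <- 100 + 50 * 0.02 + 10
  acceptor <- 50 + 10
  fret <- 150 + (donor - 10) * 0.57 + (acceptor - 10) * 0.26 + 10
  tr <- data.frame(cell_id = "c", cycle = 1, donor = donor, fret = fret,
                   acceptor = acceptor, bg_donor = 10, bg_fret = 10,
                   bg_acceptor = 10)
  expect_equal(correct_ratio(tr, bt)$ratio, 1.5, tolerance = 1e-12)
})

test_that("render/correct is the identity on noise-free synthetic cells", {
  for (i in 1:25) {
    set.seed(1000 + i)
    optics <- noise_free(
      bt_donor_to_fret = runif(1, 0, 0.8),
      bt_acceptor_to_fret = runif(1, 0, 0.6),
      bt_acceptor_to_donor = runif(1, 0, 0.1),
      background_donor = runif(1, 0, 50),
      background_fret = runif(1, 0, 50),
      background_acceptor = runif(1, 0, 50))
    ratio <- runif(20, 0.5, 3.5)
    obs <- render_fret_channels(ratio, optics, seed = i)
    bt <- bleedthrough(optics$bt_donor_to_fret, optics$bt_acceptor_to_fret,
                       optics$bt_acceptor_to_donor)
    expect_lt(max(abs(correct_ratio(obs, bt)$ratio - ratio)), 1e-9)
  }
})

test_that("ratio is invariant to background shifts and channel scaling", {
  optics <- noise_free()
  ratio <- seq(1, 2.5, length.out = 10)
  obs <- render_fret_channels(ratio, optics, seed = 2)
  bt <- bleedthrough(0.57, 0.26, 0.02)
  base <- correct_ratio(obs, bt)$ratio
  shifted <- obs
  shifted$fret <- shifted$fret + 37.5
  shifted$bg_fret <- shifted$bg_fret + 37.5
  expect_equal(correct_ratio(shifted, bt)$ratio, base, tolerance = 1e-12)
  scaled <- obs
  for (ch in c("donor", "fret", "acceptor")) {
    bg <- paste0("bg_", ch)
    scaled[[ch]] <- (scaled[[ch]] - scaled[[bg]]) * 4.2 + scaled[[bg]]
  }
  expect_equal(correct_ratio(scaled, bt)$ratio, base, tolerance = 1e-12)
})

test_that("non-positive denominators are flagged invalid, not dropped", {
  tr <- data.frame(cell_id = "c", cycle = 1:3, donor = c(110, 10, 110),
                   fret = 210, acceptor = 10, bg_donor = 10, bg_fret = 10,
                   bg_acceptor = 10)
  rt <- correct_ratio(tr, bleedthrough(0, 0, 0))
  expect_equal(rt$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(rt$ratio[2]))
  all_bad <- transform(tr, donor = 10)
  expect_error(correct_ratio(all_bad, bleedthrough(0, 0, 0)),
               "no valid cycle")
})

test_that("bleed-through slopes recover exact proportionality", {
  tr <- data.frame(cell_id = "d", cycle = 1:5, donor = c(110, 210, 60, 160, 510),
                   fret = NA, acceptor = 10, mrfp = 10, bg_donor = 10,
                   bg_fret = 10, bg_acceptor = 10, bg_mrfp = 10)
  tr$fret <- (tr$donor - 10) * 0.5 + 10
  acc <- data.frame(cell_id = "a", cycle = 1:2, donor = 10 + 0.02 * c(100, 200),
                    fret = 10 + 0.26 * c(100, 200),
                    acceptor = 10 + c(100, 200), mrfp = 10, bg_donor = 10,
                    bg_fret = 10, bg_acceptor = 10, bg_mrfp = 10)
  bt <- estimate_bleedthrough(tr, acc)
  expect_equal(bt$bt_donor_to_fret, 0.5, tolerance = 1e-12)
  expect_equal(bt$bt_acceptor_to_fret, 0.26, tolerance = 1e-12)
  expect_equal(bt$bt_acceptor_to_donor, 0.02, tolerance = 1e-12)
})

test_that("bleed-through recovery is exact on noise-free rendered controls", {
  optics <- noise_free(bt_donor_to_fret = 0.43, bt_acceptor_to_fret = 0.31,
                       bt_acceptor_to_donor = 0.015)
  bt <- estimate_bleedthrough(
    render_control_channels("donor", optics, 8, 10, seed = 5),
    render_control_channels("acceptor", optics, 8, 10, seed = 6))
  expect_equal(bt$bt_donor_to_fret, 0.43, tolerance = 1e-12)
  expect_equal(bt$bt_acceptor_to_fret, 0.31, tolerance = 1e-12)
  expect_equal(bt$bt_acceptor_to_donor, 0.015, tolerance = 1e-12)
  bad <- render_control_channels("donor", optics, 2, 3, seed = 1)
  bad$donor <- bad$bg_donor
  expect_error(estimate_bleedthrough(bad, render_control_channels(
    "acceptor", optics, 2, 3, seed = 1)), "degenerate")
})

test_that("SOCE metrics follow the window definitions exactly", {
  mk_ratio <- function(values) data.frame(cell_id = "c",
                                          cycle = seq_along(values),
                                          time_s = NA_real_,
                                          ratio = values, valid = TRUE)
  # constant trace
  m <- extract_soce_metrics(mk_ratio(rep(1, 100)))
  expect_equal(unlist(m[, -1]), c(baseline = 1, er_response = 0,
                                  pm_response = 0))
  # piecewise trace: peak 1.8 at cycle 15, second peak 1.5 at cycle 60
  v <- rep(1, 100); v[15] <- 1.8; v[60] <- 1.5
  m <- extract_soce_metrics(mk_ratio(v))
  expect_equal(unlist(m[, -1]), c(baseline = 1, er_response = 0.8,
                                  pm_response = 0.5))
  # monotonically decreasing trace: ER max sits at the window start
  v <- seq(2, 1, length.out = 100)
  m <- extract_soce_metrics(mk_ratio(v))
  expect_equal(m$er_response, v[9] - mean(v[1:9]))
  expect_lte(m$er_response, 0)
})

test_that("raising a cycle inside the ER window never lowers the response", {
  v <- rep(1, 100); v[15] <- 1.6
  base <- extract_soce_metrics(data.frame(cell_id = "c", cycle = 1:100,
                                          time_s = NA, ratio = v,
                                          valid = TRUE))$er_response
  for (cyc in c(10, 15, 20, 25)) {
    v2 <- v; v2[cyc] <- v2[cyc] + 0.5
    up <- extract_soce_metrics(data.frame(cell_id = "c", cycle = 1:100,
                                          time_s = NA, ratio = v2,
                                          valid = TRUE))$er_response
    expect_gte(up, base)
  }
})

test_that("metrics error names an all-invalid window", {
  v <- rep(1, 100)
  rt <- data.frame(cell_id = "c", cycle = 1:100, time_s = NA, ratio = v,
                   valid = TRUE)
  short <- rt[1:50, ]
  expect_error(extract_soce_metrics(short), "PM search")
  rt$valid[47:49] <- FALSE
  expect_error(extract_soce_metrics(rt), "PM reference")
})

test_that("mRFP gating uses strict inequalities and flags the boundary", {
  mk <- function(level) data.frame(cell_id = "c", cycle = 1:4,
                                   donor = 1, fret = 1, acceptor = 1,
                                   mrfp = level + 10, bg_donor = 0,
                                   bg_fret = 0, bg_acceptor = 0,
                                   bg_mrfp = 10)
  expect_equal(classify_mrfp(mk(0.4)), "neg")
  expect_equal(classify_mrfp(mk(0.6)), "pos")
  expect_warning(lab <- classify_mrfp(mk(0.5)), "gate")
  expect_equal(lab, "pos")
  expect_equal(classify_mrfp(mk(0.4)), classify_mrfp(mk(0.4)))  # idempotent
  no_mrfp <- mk(1)[, setdiff(names(mk(1)), "mrfp")]
  expect_error(classify_mrfp(no_mrfp), "mrfp")
})

test_that("population summaries report mean, SEM and n", {
  metrics <- data.frame(cell_id = c("a", "b"), baseline = c(1, 2),
                        er_response = c(0.5, 0.7), pm_response = c(0.2, 0.4))
  ratios <- data.frame(cell_id = rep(c("a", "b"), each = 2),
                       cycle = c(1, 2, 1, 2), time_s = 0,
                       ratio = c(1, 1, 2, 2), valid = TRUE)
  s <- summarize_population(ratios, metrics,
                            groups = c(a = "g1", b = "g1"))
  row <- s$per_cycle[s$per_cycle$cycle == 1, ]
  expect_equal(row$mean, 1.5)
  expect_equal(row$sem, 0.5)   # sd 0.7071 / sqrt(2)
  expect_equal(row$n, 2)
  # single cell: SEM undefined
  s1 <- summarize_population(metrics = metrics[1, ],
                             groups = c(a = "g1"))
  expect_true(all(is.na(s1$per_metric$sem)))
  expect_true(all(s1$per_metric$n == 1))
  # identical cells: SEM zero
  s0 <- summarize_population(ratios = transform(ratios, ratio = 1.2),
                             groups = c(a = "g1", b = "g1"))
  expect_true(all(s0$per_cycle$sem == 0))
})
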