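test_that("status classification follows the +/- thresholds strictly", {
  k4 <- default_thresholds("H3K4me3")
  k27 <- default_thresholds("H3K27me3")
  expect_equal(classify_status(4.5, k4), "plus")
  expect_equal(classify_status(1.2, k27), "indeterminate")
  expect_equal(classify_status(0, k4), "minus")
  expect_equal(classify_status(0, k27), "minus")
  # boundary values are indeterminate (strict inequalities)
  expect_equal(classify_status(4, k4), "indeterminate")
  expect_equal(classify_status(3, k4), "indeterminate")
})

test_that("transition calls require crossing both thresholds", {
  k27 <- default_thresholds("H3K27me3")
  expect_equal(call_transition(2.0, 0.5, k27), "loss")
  expect_equal(call_transition(0.5, 2.0, k27), "gain")
  expect_equal(call_transition(1.2, 1.3, k27), "indeterminate")
  expect_equal(call_transition(2.0, 1.2, k27), "indeterminate")
  expect_equal(call_transition(2.0, 2.5, k27), "stable")
  expect_equal(call_transition(0.2, 0.5, k27), "stable")
})

test_that("condition swap maps loss to gain and increase to decrease", {
  set.seed(3)
  th <- default_thresholds("H3K27me3")
  a <- runif(500, 0, 3); b <- runif(500, 0, 3)
  ab <- call_transition(a, b, th)
  ba <- call_transition(b, a, th)
  expect_equal(ba[ab == "loss"], rep("gain", sum(ab == "loss")))
  expect_equal(ba[ab == "gain"], rep("loss", sum(ab == "gain")))
  expect_equal(ba[ab == "stable"], rep("stable", sum(ab == "stable")))
  dm <- delta_mark(a, b); md <- delta_mark(b, a)
  expect_equal(md[dm == "increase"], rep("decrease", sum(dm == "increase")))
  expect_equal(md[dm == "decrease"], rep("increase", sum(dm == "decrease")))
})

test_that("raising hi or lowering lo never grows the called sets", {
  set.seed(4)
  rpm <- runif(1000, 0, 6)
  th1 <- mark_thresholds(hi = 2, lo = 1)
  th2 <- mark_thresholds(hi = 3, lo = 1)    # higher hi
  th3 <- mark_thresholds(hi = 2, lo = 0.5)  # lower lo
  expect_lte(sum(classify_status(rpm, th2) == "plus"),
             sum(classify_status(rpm, th1) == "plus"))
  expect_lte(sum(classify_status(rpm, th3) == "minus"),
             sum(classify_status(rpm, th1) == "minus"))
})

test_that("coordinated switch categories match the canonical patterns", {
  mk <- function(a4, b4, a27, b27) {
    to_rpm <- function(s, th) switch(s, plus = th$hi + 1, minus = th$lo / 2,
                                     ind = (th$hi + th$lo) / 2)
    k4th <- default_thresholds("H3K4me3"); k27th <- default_thresholds("H3K27me3")
    k4 <- mark_status_table(
      data.frame(gene_id = "g", rpm_max = to_rpm(a4, k4th)),
      data.frame(gene_id = "g", rpm_max = to_rpm(b4, k4th)), k4th, "H3K4me3")
    k27 <- mark_status_table(
      data.frame(gene_id = "g", rpm_max = to_rpm(a27, k27th)),
      data.frame(gene_id = "g", rpm_max = to_rpm(b27, k27th)), k27th, "H3K27me3")
    transition_table(k4, k27)$category
  }
  # repressive-mark loss with active-mark gain: the coordinated activation
  expect_equal(mk("minus", "plus", "plus", "minus"), "K27_to_K4")
  # bivalent promoter resolving by losing the repressive mark only
  expect_equal(mk("plus", "plus", "plus", "minus"), "Bi_to_K4")
  # coordinated repression
  expect_equal(mk("plus", "minus", "minus", "plus"), "K4_to_K27")
  # de novo repressive mark on an unmarked promoter
  expect_equal(mk("minus", "minus", "minus", "plus"), "none_to_K27")
  expect_equal(mk("minus", "minus", "plus", "minus"), "loss_only")
  expect_equal(mk("plus", "plus", "minus", "plus"), "gain_only")
  expect_equal(mk("plus", "plus", "minus", "minus"), "stable")
  expect_equal(mk("ind", "plus", "minus", "minus"), "other")
})

test_that("categories partition the gene set", {
  set.seed(9)
  n <- 800
  k4th <- default_thresholds("H3K4me3")
  k27th <- default_thresholds("H3K27me3")
  k4 <- mark_status_table(
    data.frame(gene_id = sprintf("g%03d", 1:n), rpm_max = runif(n, 0, 8)),
    data.frame(gene_id = sprintf("g%03d", 1:n), rpm_max = runif(n, 0, 8)),
    k4th, "H3K4me3")
  k27 <- mark_status_table(
    data.frame(gene_id = sprintf("g%03d", 1:n), rpm_max = runif(n, 0, 3)),
    data.frame(gene_id = sprintf("g%03d", 1:n), rpm_max = runif(n, 0, 3)),
    k27th, "H3K27me3")
  tt <- transition_table(k4, k27)
  expect_equal(nrow(tt), n)
  expect_false(any(is.na(tt$category)))
  expect_equal(sum(table(tt$category)), n)
  # the four headline categories are consistent with their definitions
  expect_true(all(tt$k27_transition[tt$category == "K27_to_K4"] == "loss" &
                    tt$k4_transition[tt$category == "K27_to_K4"] == "gain"))
  expect_true(all(tt$k4_A[tt$category == "none_to_K27"] == "minus" &
                    tt$k4_B[tt$category == "none_to_K27"] == "minus" &
                    tt$k27_transition[tt$category == "none_to_K27"] == "gain"))
})

test_that("continuous mark change classifies at the 0.4 cutoff", {
  expect_equal(delta_mark(1.0, 1.8), "increase")   # Atoh8-like pattern
  expect_equal(delta_mark(1.0, 0.6), "decrease")   # Parvb-like pattern
  expect_equal(delta_mark(1.0, 1.3), "none")
  expect_equal(delta_mark(1.0, 1.5, delta = 0.5), "increase")  # >= is inclusive
})

test_that("MeDIP screen applies the low-to-high rule", {
  rpm_A <- data.frame(gene_id = c("g1", "g2", "g3"),
                      rpm_max = c(1.5, 2.5, 0.5))
  rpm_B <- data.frame(gene_id = c("g1", "g2", "g3"),
                      rpm_max = c(4.2, 6.0, 3.9))
  expect_equal(medip_screen(rpm_A, rpm_B), "g1")
})
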