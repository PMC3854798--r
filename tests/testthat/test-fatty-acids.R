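test_that("trait definitions partition the measured panel", {
  defs <- fa_trait_definitions()
  expect_setequal(c(defs$groups$SFA, defs$groups$UFA), defs$fatty_acids)
  expect_length(intersect(defs$groups$SFA, defs$groups$UFA), 0)
  expect_setequal(c(defs$groups$MUFA, defs$groups$PUFA), defs$groups$UFA)
  expect_length(intersect(defs$groups$MUFA, defs$groups$PUFA), 0)
  ## even-chain membership only
  expect_false("C13:0" %in% defs$groups$C6toC14)
  expect_false("C15:0" %in% defs$groups$C6toC14)
})

test_that("published composition fixture carries the printed values", {
  mm <- table1_means()
  expect_equal(unname(mm["C16:0"]), 28.95)
  expect_equal(unname(mm["C13:0"]), 0.10)
  defs <- fa_trait_definitions()
  expect_equal(sum(mm[defs$fatty_acids]), 90.16)
})

test_that("groups and indices derive correctly per cow", {
  tbl <- random_fa_table(n = 25)
  d <- derive_fa_traits(tbl)
  defs <- fa_trait_definitions()
  ## group sums: SFA + UFA equals the total measured FA, exactly
  total <- rowSums(tbl[, defs$fatty_acids])
  expect_equal(d$SFA + d$UFA, total)
  expect_equal(d$MUFA + d$PUFA, d$UFA)
  ## linearity: group mean equals sum of member means
  expect_equal(mean(d$SFA), sum(colMeans(tbl[, defs$groups$SFA])))
  ## indices live in [0,1]
  for (ix in names(defs$indices))
    expect_true(all(d[[ix]] >= 0 & d[[ix]] <= 1, na.rm = TRUE))
})

test_that("degenerate group and index values behave as defined", {
  tbl <- random_fa_table(n = 3)
  defs <- fa_trait_definitions()
  tbl[1, defs$groups$UFA] <- 0
  expect_message(d <- derive_fa_traits(tbl), "CLAindex undefined")
  expect_equal(d$UFA[1], 0)
  expect_equal(d$MUFA[1], 0)
  expect_equal(d$PUFA[1], 0)
  expect_equal(d$C14index[1], 0)          # zero product, positive substrate
  ## product = substrate gives exactly one half
  tbl2 <- random_fa_table(n = 1)
  tbl2[["C14:1c9"]] <- tbl2[["C14:0"]] <- 2
  expect_equal(derive_fa_traits(tbl2)$C14index, 0.5)
  expect_error(derive_fa_traits(tbl2[, -which(names(tbl2) == "C16:0")]),
               "C16:0")
})

test_that("index of printed means is consistent with the printed index mean", {
  mm <- table1_means()
  c14 <- mm[["C14:1c9"]] / (mm[["C14:1c9"]] + mm[["C14:0"]])
  expect_equal(c14, 0.0791, tolerance = 1e-3)
  printed <- table1_summary()
  expect_lt(abs(c14 - printed$mean[printed$trait == "C14index"]),
            0.005)                  # mean of ratios vs ratio of means
})

test_that("trait summaries follow the printed conventions", {
  p <- data.frame(const = c(1, 1, 1, 1), two = c(2, 4, NA, NA))
  s <- summarize_traits(p)
  expect_equal(s$mean, c(1, 3))
  expect_equal(s$sd, c(0, sqrt(2)))
  expect_equal(s$cv, c(0, sqrt(2) / 3 * 100))
  expect_equal(s$cv[2], 47.14, tolerance = 1e-3)
  expect_equal(s$median, c(1, 3))
  expect_message(s0 <- summarize_traits(data.frame(z = c(-1, 1))),
                 "CV undefined")
  expect_true(is.na(s0$cv))
})

test_that("group means on the printed fixture reconstruct the printed rows", {
  mm <- table1_means()
  defs <- fa_trait_definitions()
  printed <- table1_summary()
  pm <- stats::setNames(printed$mean, printed$trait)
  for (g in c("SFA", "UFA", "MUFA", "PUFA", "C6toC14"))
    expect_equal(sum(mm[defs$groups[[g]]]), unname(pm[g]), tolerance = 1e-10)
})
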