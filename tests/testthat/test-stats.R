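test_that("sign alignment flips anti-aligned composites and is idempotent", {
  coh <- fixture_cohort(n_subjects = 10, seed = 2)
  z <- standardize(coh, fit_scaler(coh))
  d <- default_battery()$direction
  proxy <- drop(as.matrix(z[, default_battery()$measure]) %*% d) / 8

  al_pos <- align_sign(proxy, z)
  expect_equal(sign_factor(al_pos), 1)
  expect_equal(al_pos$aligned, proxy)

  al_neg <- align_sign(-proxy, z)
  expect_equal(sign_factor(al_neg), -1)
  expect_equal(al_neg$aligned, proxy)

  again <- align_sign(al_neg$aligned, z)
  expect_equal(sign_factor(again), 1)

  expect_error(align_sign(rep(1, nrow(z)), z), "zero variance")
  expect_error(align_sign(proxy[-1], z), "one raw score per record")
})

test_that("improving any single measure raises the aligned PCA composite", {
  coh <- generate_cohort(preset_config("published-linear", n = 150, seed = 3))
  z <- standardize(coh, fit_scaler(coh))
  zm <- as.matrix(z[, default_battery()$measure])
  fit <- fit_pca(z, n_components = 1, battery = default_battery())
  al <- align_sign(pca_composite(fit), z, method = "pca")
  b <- default_battery()
  sf <- sign_factor(al)
  for (rec in c(1, 7, 20)) {
    for (k in seq_len(8)) {
      pert <- zm
      pert[rec, k] <- pert[rec, k] + b$direction[k]  # +1 SD of improvement
      score <- sf * drop(sweep(pert, 2, fit$center) %*% fit$loadings)[rec]
      expect_gt(score, al$aligned[rec])
    }
  }
})

test_that("rm_anova reproduces the closed-form paired t on known differences", {
  scores <- tibble::tibble(
    subject = rep(c("a", "b", "c"), each = 2),
    condition = factor(rep(c("MK", "MCK"), 3), levels = c("MK", "MCK")),
    aligned = c(0, 1, 0, 2, 0, 3)  # differences 1, 2, 3
  )
  res <- rm_anova(scores)
  expect_equal(res$t, 3.464102, tolerance = 1e-6)
  expect_equal(res$statistic, 12, tolerance = 1e-6)
  expect_equal(res$p_value, 0.074180, tolerance = 1e-5)
  expect_equal(res$df, c(1L, 2L))
  expect_equal(res$mean_difference, 2)
})

test_that("rm_anova equals the paired t-test and the aov reduction", {
  for (s in 1:25) {
    np <- withr::with_seed(s, sample(3:15, 1))
    v1 <- withr::with_seed(10 + s, rnorm(np))
    v2 <- withr::with_seed(200 + s, rnorm(np, mean = 0.5))
    scores <- tibble::tibble(
      subject = rep(sprintf("s%02d", 1:np), each = 2),
      condition = factor(rep(c("A", "B"), np), levels = c("A", "B")),
      aligned = as.vector(rbind(v1, v2))
    )
    res <- rm_anova(scores)
    tt <- t.test(v2, v1, paired = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-9)
  }
  # one within-subject factor, two levels: F of aov(Error(subject)) matches
  np <- 9
  v1 <- withr::with_seed(77, rnorm(np))
  v2 <- withr::with_seed(78, rnorm(np, mean = 1))
  df <- data.frame(
    subject = factor(rep(1:np, 2)),
    condition = factor(rep(c("A", "B"), each = np)),
    y = c(v1, v2)
  )
  aovtab <- summary(stats::aov(y ~ condition + Error(subject), data = df))
  f_aov <- aovtab[["Error: Within"]][[1]]["condition", "F value"]
  scores <- tibble::tibble(
    subject = as.character(df$subject),
    condition = factor(df$condition, levels = c("A", "B")),
    aligned = df$y
  )
  expect_equal(rm_anova(scores)$statistic, f_aov, tolerance = 1e-9)
})

test_that("rm_anova boundary and error cases", {
  sym <- tibble::tibble(
    subject = rep(c("a", "b"), each = 2),
    condition = factor(rep(c("A", "B"), 2), levels = c("A", "B")),
    aligned = c(0, -1, 0, 1)  # differences -1, +1
  )
  res <- rm_anova(sym)
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p_value, 1)

  const <- sym
  const$aligned <- c(0, 1, 0, 1)  # all differences equal
  expect_error(rm_anova(const), "zero variance")

  incomplete <- sym[-4, ]
  expect_error(rm_anova(incomplete), "incomplete pair.*'b'")

  one_pair <- sym[1:2, ]
  expect_error(rm_anova(one_pair), "at least 2 complete pairs")
})

test_that("per-measure paired tests report direction-consistent improvement", {
  coh <- generate_cohort(preset_config("published-linear", n = 400, seed = 5))
  mt <- measure_tests(coh)
  expect_equal(nrow(mt), 8)
  # at n = 400 every Table-2 mean shift is detectable and runs in the
  # direction of improvement under MCK
  expect_true(all(mt$improved))
  expect_true(mt$significant[mt$measure == "10MWT"])
  # oracle check on one measure
  cp <- tidyr::pivot_wider(coh[c("subject", "condition", "TUG")],
                           names_from = condition, values_from = TUG)
  tt <- t.test(cp$MCK - cp$MK)
  expect_equal(mt$p_value[mt$measure == "TUG"], tt$p.value, tolerance = 1e-12)
})

test_that("summaries reproduce hand-computed per-condition moments", {
  coh <- fixture_cohort(n_subjects = 4, seed = 6)
  z <- standardize(coh, fit_scaler(coh))
  proxy <- drop(as.matrix(z[, default_battery()$measure]) %*%
                  default_battery()$direction) / 8
  al <- align_sign(proxy, z, method = "pca")
  summ <- summarize_composite(al, data = coh)
  expect_setequal(unique(summ$variable), c("composite_pca", default_battery()$measure))

  mk <- al$aligned[al$condition == "MK"]
  row <- summ[summ$variable == "composite_pca" & summ$condition == "MK", ]
  expect_equal(row$n, 4L)
  expect_equal(row$mean, mean(mk))
  expect_equal(row$sd, sd(mk))
  expect_equal(row$se, sd(mk) / 2)

  row_b <- summ[summ$variable == "BERG" & summ$condition == "MCK", ]
  expect_equal(row_b$mean, mean(coh$BERG[coh$condition == "MCK"]))

  # permutation invariance
  perm <- withr::with_seed(1, sample(nrow(coh)))
  summ2 <- summarize_composite(al[perm, ], data = coh[perm, ])
  expect_equal(dplyr::arrange(summ2, variable, condition),
               dplyr::arrange(summ, variable, condition))
})

test_that("single-record conditions report missing SD and SE", {
  coh <- fixture_cohort(n_subjects = 1, seed = 2)
  z <- standardize(coh, tibble::tibble(measure = default_battery()$measure,
                                       mean = 0, sd = 1))
  al <- align_sign(c(-1, 1), z)
  summ <- summarize_composite(al)
  expect_true(all(is.na(summ$sd)))
  expect_true(all(is.na(summ$se)))
})

test_that("arrow data has one arrow per subject with consistent group means", {
  coh <- fixture_cohort(n_subjects = 9, seed = 8)
  z <- standardize(coh, fit_scaler(coh))
  proxy <- drop(as.matrix(z[, default_battery()$measure]) %*%
                  default_battery()$direction) / 8
  al <- align_sign(proxy, z)
  arrows <- arrow_plot_data(al)
  expect_equal(nrow(arrows), 9)
  expect_equal(arrows$from[1], "MK")
  expect_equal(arrows$to[1], "MCK")
  gm <- attr(arrows, "group_means")
  expect_equal(
    mean(arrows$delta),
    gm$mean_score[gm$condition == "MCK"] - gm$mean_score[gm$condition == "MK"],
    tolerance = 1e-12
  )

  # identical scores under both conditions give a zero-length arrow
  al2 <- al
  al2$aligned[al2$subject == "S001"] <- 0.5
  expect_equal(arrow_plot_data(al2)$delta[1], 0)
})

test_that("aligned composites rank the better condition higher in most seeds", {
  n_seeds <- 100
  pca_higher <- logical(n_seeds)
  ae_higher <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    coh <- generate_cohort(cohort_config(n_subjects = 9, seed = 5000 + s))
    z <- standardize(coh, fit_scaler(coh))
    fit <- fit_pca(z, 1, battery = default_battery())
    al <- align_sign(pca_composite(fit), z)
    gm <- tapply(al$aligned, al$condition, mean)
    pca_higher[s] <- gm[["MCK"]] > gm[["MK"]]
    m <- train_ae(z, epochs = 400, patience = 50, seed = 5000 + s)
    alae <- align_sign(encode(m, z), z)
    gmae <- tapply(alae$aligned, alae$condition, mean)
    ae_higher[s] <- gmae[["MCK"]] > gmae[["MK"]]
  }
  expect_gte(mean(pca_higher), 0.95)
  expect_gte(mean(ae_higher), 0.95)
})
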