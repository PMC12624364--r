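test_that("the design coding follows the stated conventions", {
  ph <- data.frame(subject_id = c("a", "b", "c", "d"),
                   site = "s1",
                   diagnosis = c("ASD", "ASD", "NA", "NA"),
                   sex = c("F", "M", "F", "M"),
                   age = c(9, 10, 11, 12), mean_fd = c(0.1, 0.2, 0.1, 0.2))
  X <- buildDesign(ph)
  # autistic female: (-1, +1, -1)
  expect_equal(unname(X[1, c("diagnosis", "sex", "dx_by_sex")]),
               c(-1, 1, -1))
  expect_lt(abs(mean(X[, "age_centered"])), 1e-12)
  expect_false(is.null(attr(X, "coding")))
  phM <- ph; phM$sex <- "M"
  expect_error(buildDesign(phM), "constant")
  phBad <- ph; phBad$diagnosis[2] <- "autism"
  expect_error(buildDesign(phBad), "unknown diagnosis")
})

test_that("GLM fits agree with the normal-equations oracle", {
  expect_equal(fitGlm(rep(0, 30),
                      cbind(intercept = rep(1, 30),
                            x = rnorm(30)))$coefficients$beta,
               c(0, 0))
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(12:40, 1); k <- sample(2:5, 1)
    X <- cbind(1, matrix(rnorm(n * (k - 1)), n, k - 1))
    colnames(X) <- paste0("c", seq_len(k))
    y <- rnorm(n)
    fit <- fitGlm(y, X)
    expect_lt(max(abs(fit$coefficients$beta - oracleOls(y, X))), 1e-8)
    # standard errors against lm as an independent route
    lf <- summary(lm(y ~ X - 1))
    expect_lt(max(abs(fit$coefficients$se - lf$coefficients[, 2])), 1e-8)
    expect_lt(max(abs(fit$coefficients$p - lf$coefficients[, 4])), 1e-10)
  }
})

test_that("balanced noiseless cells reproduce closed-form contrasts", {
  mu <- c(FA = 1.2, MA = 1.0, FN = 0.9, MN = 1.0)
  ph <- data.frame(
    subject_id = sprintf("s%02d", 1:20), site = "s1",
    diagnosis = rep(c("ASD", "ASD", "NA", "NA"), 5),
    sex = rep(c("F", "M", "F", "M"), 5),
    age = rep(c(9, 10, 11, 12, 10), 4), mean_fd = 0.1)
  cell <- paste0(ph$sex, ifelse(ph$diagnosis == "ASD", "A", "N"))
  y <- mu[cell]
  X <- buildDesign(ph, c("intercept", "diagnosis", "sex", "dx_by_sex"))
  fit <- fitGlm(y, X)
  cf <- fit$coefficients
  expect_equal(cf$beta[cf$term == "dx_by_sex"],
               (mu["MA"] + mu["FN"] - mu["FA"] - mu["MN"]) / 4,
               ignore_attr = TRUE)
  expect_equal(cf$beta[cf$term == "dx_by_sex"], -0.075, ignore_attr = TRUE)
  # main effects are their cell-mean contrasts too
  expect_equal(cf$beta[cf$term == "diagnosis"],
               (mu["FN"] + mu["MN"] - mu["FA"] - mu["MA"]) / 4,
               ignore_attr = TRUE)
})

test_that("region-wise models emit one row per region and term", {
  coh <- makeCohort(cohortConfig(cells = c(MA = 8, FA = 8, MN = 8, FN = 8),
                                 nSites = 1, nRegions = 6), seed = 31)
  se <- regionalFeatures(coh$features, coh$phenotypes)
  tab <- regionEffects(se)
  expect_equal(nrow(tab), 6 * 3)
  expect_setequal(unique(tab$term), c("diagnosis", "sex", "dx_by_sex"))
  expect_false("p_fdr" %in% names(tab))      # uncorrected by default
  tab2 <- regionEffects(se, fdr = TRUE)
  expect_true("p_fdr" %in% names(tab2))
})

test_that("subgroup models recover sex-specific diagnostic effects", {
  ge <- matrix(0, 4, 3)
  ge[1, 1] <- -0.3; ge[1, 3] <- -0.3   # female-only ASD elevation
  coh <- makeCohort(cohortConfig(cells = c(MA = 60, FA = 60, MN = 60,
                                           FN = 60), nSites = 1,
                                 nRegions = 4, groupEffects = ge,
                                 subjectSd = 0.3), seed = 32)
  se <- regionalFeatures(coh$features, coh$phenotypes)
  tab <- subgroupEffects(se, "sex", "diagnosis", regions = "region_001")
  bF <- tab$beta[tab$stratum == "sex=F"]
  bM <- tab$beta[tab$stratum == "sex=M"]
  expect_lt(abs(bF - (-0.6)), 0.12)          # within-female beta = dx + int
  expect_lt(abs(bM), 0.12)
  # a sub-8-subject stratum runs with a small-sample warning
  cohS <- makeCohort(cohortConfig(cells = c(MA = 20, FA = 3, MN = 20,
                                            FN = 4), nSites = 1,
                                  nRegions = 3), seed = 33)
  seS <- regionalFeatures(cohS$features, cohS$phenotypes)
  expect_warning(subgroupEffects(seS, "sex", "diagnosis"), "only")
  # determinism
  expect_identical(subgroupEffects(se, "sex", "diagnosis"),
                   subgroupEffects(se, "sex", "diagnosis"))
})

test_that("rCVR-FC association models recover injected slopes with FDR", {
  set.seed(41)
  n <- 120
  ph <- smallPheno(n, nSites = 1, seed = 41)
  rcvr <- rnorm(n, 3.5, 0.5)
  b <- 0.25
  fc <- matrix(rnorm(n * 10, 0.3, 0.2), n, 10,
               dimnames = list(ph$subject_id, paste0("t", 1:10)))
  fc[, 1] <- 0.1 + b * rcvr + rnorm(n, 0, 0.15)
  tab <- cvrFcAssociation(rcvr, fc, ph, "females")
  expect_equal(nrow(tab), 10L)
  hit <- tab[tab$target == "t1", ]
  expect_lt(abs(hit$beta - b), 2 * hit$se)
  expect_lt(hit$p_fdr, 0.05)
  # unrelated targets stay non-significant after FDR
  expect_true(all(tab$p_fdr[tab$target != "t1"] > 0.05))
  # zero-variance predictor in a subgroup is an error
  expect_error(cvrFcAssociation(rep(1, n), fc, ph, "males"),
               "zero-variance")
})

test_that("BH adjustment matches the step-up oracle and its invariances", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  set.seed(51)
  for (i in 1:200) {
    p <- runif(sample(3:90, 1))
    expect_equal(bhFdr(p), oracleBH(p), tolerance = 1e-12)
  }
  p <- runif(50)
  adj <- bhFdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))   # monotone in rank
  perm <- sample(50)
  expect_equal(bhFdr(p[perm]), adj[perm])            # order-invariant
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
})
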