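#' Assemble a regional feature table
#'
#' Wraps a regions x subjects feature matrix (regional rCVR values or seed
#' Fisher-z values) with its phenotypes into a
#' [SummarizedExperiment::SummarizedExperiment], the unit that
#' harmonization and the group models operate on. Missing features stay NA
#' (flagged), never zero-filled. rCVR and FC families should be kept in
#' separate tables (they are harmonized in separate models).
#'
#' @param values regions x subjects numeric matrix, or subjects x regions
#'   with `subjectsInRows = TRUE`.
#' @param phenotypes data.frame with one row per subject (see
#'   [readPhenotypes()] for the required columns).
#' @param subjectsInRows set TRUE when `values` is subjects x regions.
#' @return a `SummarizedExperiment` with assay `"features"`.
#' @export
regionalFeatures <- function(values, phenotypes, subjectsInRows = FALSE) {
  if (subjectsInRows) values <- t(values)
  stopIfNot(ncol(values) == nrow(phenotypes),
            "one phenotype row per subject column is required")
  phenotypes <- validatePhenotypes(phenotypes)
  if (is.null(colnames(values))) colnames(values) <- phenotypes$subject_id
  stopIfNot(identical(colnames(values), phenotypes$subject_id),
            "feature columns and phenotype subject ids disagree")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    colData = S4Vectors::DataFrame(phenotypes, row.names = phenotypes$subject_id))
}

#' @rdname regionalFeatures
#' @param se a `SummarizedExperiment` from [regionalFeatures()].
#' @export
featureMatrix <- function(se) {
  SummarizedExperiment::assay(se, "features")
}

#' @rdname regionalFeatures
#' @export
featurePhenotypes <- function(se) {
  as.data.frame(SummarizedExperiment::colData(se))
}

# Covariate design for harmonization: diagnosis and sex under the +/-1
# coding shared with the downstream GLMs, plus mean-centered age; the
# diagnosis x sex interaction is off by default (option).
combatCovariates <- function(pheno, ageMean = NULL,
                             includeInteraction = FALSE) {
  x <- ifelse(pheno$diagnosis == "ASD", -1, 1)
  y <- ifelse(pheno$sex == "M", -1, 1)
  if (is.null(ageMean)) ageMean <- mean(pheno$age)
  X <- cbind(diagnosis = x, sex = y, age_centered = pheno$age - ageMean)
  if (includeInteraction) X <- cbind(X, dx_by_sex = x * y)
  attr(X, "ageMean") <- ageMean
  X
}

# Method-of-moments inverse-gamma hyperparameters for the scale priors.
igPriorA <- function(deltaHat) (2 * var(deltaHat) + mean(deltaHat)^2) /
  var(deltaHat)
igPriorB <- function(deltaHat) (mean(deltaHat) * var(deltaHat) +
                                  mean(deltaHat)^3) / var(deltaHat)

# Iterative conditional EB updates for one site (parametric priors:
# normal for location, inverse-gamma for squared scale).
ebSolve <- function(sdat, gHat, dHat, gBar, t2, aPrior, bPrior,
                    conv = 1e-4, maxIter = 100L) {
  n <- rowSums(!is.na(sdat))
  gOld <- gHat; dOld <- dHat
  change <- 1; count <- 0L
  gNew <- gHat; dNew <- dHat
  while (change > conv && count < maxIter) {
    gNew <- (t2 * n * gHat + dOld * gBar) / (t2 * n + dOld)
    sum2 <- rowSums(sweep(sdat, 1, gNew)^2, na.rm = TRUE)
    dNew <- (0.5 * sum2 + bPrior) / (n / 2 + aPrior - 1)
    change <- max(abs(gNew - gOld) / abs(gOld + 1e-12),
                  abs(dNew - dOld) / abs(dOld + 1e-12))
    gOld <- gNew; dOld <- dNew
    count <- count + 1L
  }
  list(gammaStar = gNew, delta2Star = dNew, iterations = count)
}

#' Fit an empirical-Bayes location/scale (ComBat) harmonization model
#'
#' Standardizes each feature by its covariate-adjusted mean and pooled SD,
#' estimates per-site location and scale effects, shrinks them toward
#' site-level parametric priors (normal for location, inverse-gamma for
#' squared scale; method-of-moments hyperparameters; iterative conditional
#' updates to tolerance 1e-4), and returns a persistable [CombatModel-class]
#' to apply with [combatTransform()]. Diagnosis, sex and mean-centered age
#' are preserved as biological covariates. With a single site the model
#' reduces to the identity.
#'
#' @param se a `SummarizedExperiment` from [regionalFeatures()].
#' @param batch name of the colData column holding the site label.
#' @param includeInteraction also preserve the diagnosis-by-sex interaction.
#' @param eb apply empirical-Bayes shrinkage (TRUE; FALSE uses the raw
#'   per-site estimates, useful for diagnostics).
#' @return a [CombatModel-class].
#' @export
combatFit <- function(se, batch = "site", includeInteraction = FALSE,
                      eb = TRUE) {
  Y <- featureMatrix(se)                      # features x subjects
  pheno <- featurePhenotypes(se)
  site <- factor(pheno[[batch]])
  ns <- table(site)
  if (any(ns < 2))
    stop("site(s) with a single subject: ",
         paste(names(ns)[ns < 2], collapse = ", "), call. = FALSE)
  X <- combatCovariates(pheno, includeInteraction = includeInteraction)
  B <- vapply(levels(site), function(l) as.numeric(site == l),
              numeric(length(site)))          # subjects x sites
  design <- cbind(B, X)
  if (qr(design)$rank < ncol(design))
    stop("rank-deficient covariate design (a covariate is confounded with site)",
         call. = FALSE)
  G <- nrow(Y); S <- nlevels(site); N <- ncol(Y)

  # per-feature OLS of Y on [site indicators, covariates]
  fit <- lm.fit(design, t(Y))
  coefs <- t(fit$coefficients)                # G x (S + p)
  siteInt <- coefs[, seq_len(S), drop = FALSE]
  covCoef <- coefs[, -seq_len(S), drop = FALSE]
  grandMean <- as.vector(siteInt %*% (as.numeric(ns) / N))
  resid <- t(fit$residuals)                   # G x N, site + covariates removed
  pooledSd <- sqrt(rowSums(resid^2) / N)
  pooledSd[pooledSd <= 0] <- 1e-12
  stand <- Y - tcrossprod(grandMean, rep(1, N)) - t(X %*% t(covCoef))
  Z <- stand / pooledSd

  gammaHat <- t(vapply(levels(site), function(l)
    rowMeans(Z[, site == l, drop = FALSE]), numeric(G)))
  deltaHat <- t(vapply(levels(site), function(l)
    apply(Z[, site == l, drop = FALSE], 1, var), numeric(G)))
  deltaHat[deltaHat <= 0] <- 1e-12

  gammaStar <- gammaHat
  delta2Star <- deltaHat
  iters <- numeric(S)
  hyper <- list()
  if (eb && S > 1) {
    for (i in seq_len(S)) {
      gBar <- mean(gammaHat[i, ]); t2 <- var(gammaHat[i, ])
      aP <- igPriorA(deltaHat[i, ]); bP <- igPriorB(deltaHat[i, ])
      sol <- ebSolve(Z[, site == levels(site)[i], drop = FALSE],
                     gammaHat[i, ], deltaHat[i, ], gBar, t2, aP, bP)
      gammaStar[i, ] <- sol$gammaStar
      delta2Star[i, ] <- sol$delta2Star
      iters[i] <- sol$iterations
      hyper[[levels(site)[i]]] <- list(gammaBar = gBar, tau2 = t2,
                                       aPrior = aP, bPrior = bP)
    }
  } else if (S == 1) {
    gammaStar[] <- 0
    delta2Star[] <- 1
  }
  new("CombatModel",
      featureNames = rownames(Y), siteLevels = levels(site),
      grandMean = grandMean, covCoef = t(covCoef),
      covariateNames = colnames(X), pooledSd = pooledSd,
      gammaStar = gammaStar, deltaStar = sqrt(delta2Star),
      gammaHat = gammaHat, deltaHat = sqrt(deltaHat),
      hyper = hyper, ageMean = attr(X, "ageMean"), iterations = iters)
}

#' Apply a fitted harmonization model
#'
#' `adjusted = pooledSd / deltaStar * (standardized - gammaStar) +
#' grandMean + covariate-predicted mean`; covariate-associated variation is
#' preserved, site location and scale are removed.
#'
#' @param model a [CombatModel-class] from [combatFit()].
#' @param se a `SummarizedExperiment` with the same feature labels.
#' @param batch name of the colData site column.
#' @return a `SummarizedExperiment` with harmonized features.
#' @export
combatTransform <- function(model, se, batch = "site") {
  Y <- featureMatrix(se)
  pheno <- featurePhenotypes(se)
  stopIfNot(identical(rownames(Y), model@featureNames),
            "feature labels differ from the fitted model")
  site <- as.character(pheno[[batch]])
  unseen <- setdiff(unique(site), model@siteLevels)
  if (length(unseen))
    stop("unseen site label(s): ", paste(unseen, collapse = ", "),
         call. = FALSE)
  inter <- "dx_by_sex" %in% model@covariateNames
  X <- combatCovariates(pheno, ageMean = model@ageMean,
                        includeInteraction = inter)
  pred <- model@grandMean + t(X %*% model@covCoef)   # G x N
  Z <- (Y - pred) / model@pooledSd
  si <- match(site, model@siteLevels)
  adj <- (Z - t(model@gammaStar[si, , drop = FALSE])) /
    t(model@deltaStar[si, , drop = FALSE])
  out <- adj * model@pooledSd + pred
  se2 <- se
  SummarizedExperiment::assay(se2, "features") <- out
  se2
}

#' Fit and apply harmonization in one call
#'
#' @inheritParams combatFit
#' @return list with `se` (harmonized features) and `model`.
#' @export
combatHarmonize <- function(se, batch = "site", includeInteraction = FALSE) {
  model <- combatFit(se, batch = batch,
                     includeInteraction = includeInteraction)
  list(se = combatTransform(model, se, batch = batch), model = model)
}
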