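#' Build a coded design matrix from phenotypes
#'
#' Effect coding: diagnosis ASD = -1, NA (non-autistic) = +1; sex M = -1,
#' F = +1; the diagnosis-by-sex interaction is the product of the codes.
#' Age is centered at the mean of the fitted sample. The coding is recorded
#' in the `"coding"` attribute so signs are always interpretable.
#'
#' @param pheno phenotype data.frame (see [readPhenotypes()]).
#' @param terms character vector drawn from `intercept`, `diagnosis`,
#'   `sex`, `dx_by_sex`, `age_centered`, `mean_fd`, `rcvr_seed`.
#' @param rcvrSeed per-subject seed-region rCVR values (required when the
#'   `rcvr_seed` term is requested).
#' @return numeric design matrix with a `"coding"` attribute; constant
#'   requested columns raise an error.
#' @export
buildDesign <- function(pheno,
                        terms = c("intercept", "diagnosis", "sex",
                                  "dx_by_sex", "age_centered", "mean_fd"),
                        rcvrSeed = NULL) {
  known <- c("intercept", "diagnosis", "sex", "dx_by_sex", "age_centered",
             "mean_fd", "rcvr_seed")
  stopIfNot(all(terms %in% known),
            paste("unknown term(s):",
                  paste(setdiff(terms, known), collapse = ", ")))
  badDx <- setdiff(unique(pheno$diagnosis), c("ASD", "NA"))
  if (length(badDx))
    stop("unknown diagnosis level(s): ", paste(badDx, collapse = ", "),
         call. = FALSE)
  badSex <- setdiff(unique(pheno$sex), c("F", "M"))
  if (length(badSex))
    stop("unknown sex level(s): ", paste(badSex, collapse = ", "),
         call. = FALSE)
  n <- nrow(pheno)
  x <- ifelse(pheno$diagnosis == "ASD", -1, 1)
  y <- ifelse(pheno$sex == "M", -1, 1)
  cols <- list(intercept = rep(1, n), diagnosis = x, sex = y,
               dx_by_sex = x * y,
               age_centered = pheno$age - mean(pheno$age),
               mean_fd = pheno$mean_fd)
  if ("rcvr_seed" %in% terms) {
    stopIfNot(!is.null(rcvrSeed), "rcvr_seed term requested without values")
    cols$rcvr_seed <- rcvrSeed
  }
  X <- do.call(cbind, cols[terms])
  colnames(X) <- terms
  const <- vapply(terms, function(tm)
    tm != "intercept" && sd(X[, tm]) == 0, logical(1))
  if (any(const))
    stop("constant design column(s): ",
         paste(terms[const], collapse = ", "), call. = FALSE)
  attr(X, "coding") <- c(diagnosis = "ASD=-1, NA=+1",
                         sex = "M=-1, F=+1",
                         dx_by_sex = "product of codes",
                         age_centered = sprintf("centered at %.4f",
                                                mean(pheno$age)))
  X
}

#' Ordinary least-squares general linear model
#'
#' QR-based OLS with classical standard errors
#' `sigma^2 (X'X)^{-1}`, t statistics and two-sided p-values on
#' `n - k` degrees of freedom.
#'
#' @param y numeric outcome, one value per subject.
#' @param X numeric design matrix (full rank, `n > ncol`).
#' @return list of class `glmFit`: `coefficients` (data.frame term, beta,
#'   se, t, p), `df`, `sigma`, `coding` (from the design, if recorded).
#' @export
fitGlm <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y); k <- ncol(X)
  stopIfNot(nrow(X) == n, "design rows must match outcome length")
  stopIfNot(n > k, "need more subjects than design columns")
  qrX <- qr(X)
  if (qrX$rank < k)
    stop("rank-deficient design", call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- n - k
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- ifelse(se > 0, beta / se, 0)
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  structure(list(
    coefficients = data.frame(term = colnames(X), beta = as.numeric(beta),
                              se = se, t = tval, p = pval,
                              row.names = NULL),
    df = df, sigma = sqrt(sigma2), coding = attr(X, "coding")),
    class = "glmFit")
}

#' Region-wise diagnosis / sex / interaction models
#'
#' One model per region:
#' `feature ~ diagnosis + sex + dx_by_sex + age_centered + mean_fd`
#' under +/-1 coding, on (harmonized) regional features. Betas are always
#' reported signed. No multiplicity correction is applied by default — the
#' region scan is exploratory and p-values are reported uncorrected; pass
#' `fdr = TRUE` to add a BH-adjusted column per term family.
#'
#' @param se a `SummarizedExperiment` from [regionalFeatures()].
#' @param terms reported terms, default diagnosis, sex, dx_by_sex.
#' @param fdr add a BH-adjusted p column (per term, across regions).
#' @param maxMissing regions missing for more than this fraction of
#'   subjects are skipped (with a message), default 0.1.
#' @return data.frame: region, term, beta, se, t, p, n (+ `p_fdr`).
#' @export
regionEffects <- function(se, terms = c("diagnosis", "sex", "dx_by_sex"),
                          fdr = FALSE, maxMissing = 0.1) {
  Y <- featureMatrix(se)
  pheno <- featurePhenotypes(se)
  out <- list()
  for (g in rownames(Y)) {
    yv <- Y[g, ]
    ok <- !is.na(yv)
    if (mean(!ok) > maxMissing) {
      message("skipping region ", g, ": missing for ",
              sum(!ok), " subjects")
      next
    }
    X <- buildDesign(pheno[ok, , drop = FALSE],
                     c("intercept", "diagnosis", "sex", "dx_by_sex",
                       "age_centered", "mean_fd"))
    fit <- fitGlm(yv[ok], X)
    cf <- fit$coefficients
    cf <- cf[cf$term %in% terms, , drop = FALSE]
    cf$region <- g
    cf$n <- sum(ok)
    out[[g]] <- cf
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab <- tab[, c("region", "term", "beta", "se", "t", "p", "n")]
  if (fdr) {
    tab$p_fdr <- NA_real_
    for (tm in unique(tab$term)) {
      i <- tab$term == tm
      tab$p_fdr[i] <- bhFdr(tab$p[i])
    }
  }
  tab
}

#' Post-hoc subgroup models
#'
#' Within each stratum of `split` (sex by default), fits
#' `feature ~ tested term + age_centered + mean_fd` to disentangle, e.g.,
#' sex-specific diagnostic differences. Strata smaller than 8 subjects run
#' with a small-sample warning; empty strata are an error.
#'
#' @param se a `SummarizedExperiment` from [regionalFeatures()].
#' @param split stratifying variable: `"sex"` or `"diagnosis"`.
#' @param term tested predictor: `"diagnosis"` or `"sex"`.
#' @param regions subset of region names (default: all).
#' @return data.frame: region, stratum, term, beta, se, t, p, n.
#' @export
subgroupEffects <- function(se, split = c("sex", "diagnosis"),
                            term = c("diagnosis", "sex"),
                            regions = NULL) {
  split <- match.arg(split); term <- match.arg(term)
  stopIfNot(split != term, "split and tested term must differ")
  Y <- featureMatrix(se)
  pheno <- featurePhenotypes(se)
  if (is.null(regions)) regions <- rownames(Y)
  strata <- sort(unique(pheno[[split]]))
  out <- list()
  for (s in strata) {
    rows <- which(pheno[[split]] == s)
    if (!length(rows)) stop("empty stratum: ", s, call. = FALSE)
    if (length(rows) < 8)
      warning(sprintf("stratum %s=%s has only %d subjects", split, s,
                      length(rows)))
    X <- buildDesign(pheno[rows, , drop = FALSE],
                     c("intercept", term, "age_centered", "mean_fd"))
    for (g in regions) {
      fit <- fitGlm(Y[g, rows], X)
      cf <- fit$coefficients
      cf <- cf[cf$term == term, , drop = FALSE]
      cf$region <- g; cf$stratum <- paste0(split, "=", s)
      cf$n <- length(rows)
      out[[paste(g, s)]] <- cf
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab[, c("region", "stratum", "term", "beta", "se", "t", "p", "n")]
}

#' Association between seed rCVR and seed-to-target FC within subgroups
#'
#' Within the requested subgroup, each target's Fisher-z FC to the seed is
#' regressed on the subject's seed rCVR, with the complementary grouping
#' factor (diagnosis within sex subgroups, sex within diagnosis subgroups),
#' mean-centered age and mean FD as covariates. BH FDR is applied across
#' the target family within the subgroup.
#'
#' @param seedRcvr per-subject seed-region rCVR (full cohort order).
#' @param fcProfiles subjects x targets matrix of Fisher-z values (targets
#'   exclude the seed).
#' @param pheno phenotype data.frame (full cohort order).
#' @param subgroup one of `"females"`, `"males"`, `"autistic"`,
#'   `"non-autistic"`.
#' @return data.frame: target, subgroup, beta, se, t, p, p_fdr, n.
#' @export
cvrFcAssociation <- function(seedRcvr, fcProfiles, pheno,
                             subgroup = c("females", "males", "autistic",
                                          "non-autistic")) {
  subgroup <- match.arg(subgroup)
  sel <- switch(subgroup,
                females = pheno$sex == "F",
                males = pheno$sex == "M",
                autistic = pheno$diagnosis == "ASD",
                `non-autistic` = pheno$diagnosis == "NA")
  stopIfNot(any(sel), "empty subgroup")
  other <- if (subgroup %in% c("females", "males")) "diagnosis" else "sex"
  ph <- pheno[sel, , drop = FALSE]
  rv <- seedRcvr[sel]
  stopIfNot(sd(rv) > 0, "zero-variance seed rCVR in subgroup")
  X <- buildDesign(ph, c("intercept", "rcvr_seed", other, "age_centered",
                         "mean_fd"), rcvrSeed = rv)
  rows <- lapply(colnames(fcProfiles), function(tg) {
    fit <- fitGlm(fcProfiles[sel, tg], X)
    cf <- fit$coefficients
    cf <- cf[cf$term == "rcvr_seed", , drop = FALSE]
    data.frame(target = tg, subgroup = subgroup, beta = cf$beta,
               se = cf$se, t = cf$t, p = cf$p, n = sum(sel))
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- bhFdr(tab$p)
  tab
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `adj_i = min_{j >= rank(i)} m p_(j) / j`,
#' capped at 1, returned in the input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bhFdr <- function(p) {
  stopIfNot(all(is.finite(p)) && all(p >= 0 & p <= 1),
            "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
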