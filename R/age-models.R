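#' Eight-feature breakome vector for one sample
#'
#' Assembles the sample-level features used by the age models: enrichment
#' odds ratios for exons, introns, promoters, insulators and enhancers;
#' mean positive and mean absolute-negative conservation (PhyloP-style)
#' scores in +/- 20 bp windows around breaks; and the fraction of breaks
#' mapping to the mitochondrial chromosome. Delegates to
#' \code{\link{element_enrichment}} and \code{\link{conservation_profile}}.
#'
#' @param bs an \code{ssb_breakset}.
#' @param annotations list with elements \code{exon, intron, promoter,
#'   insulator, enhancer} (interval data.frames), \code{background}
#'   (interval data.frame), \code{conservation} (an \code{ssb_track}), and
#'   \code{chrM} (mitochondrial chromosome name, default "chrM").
#' @return named numeric vector of 8 features.
#' @export
sample_features <- function(bs, annotations) {
  needed <- c("exon", "intron", "promoter", "insulator", "enhancer",
              "background", "conservation")
  missing <- setdiff(needed, names(annotations))
  if (length(missing))
    stop("missing annotation(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ors <- vapply(c("exon", "intron", "promoter", "insulator", "enhancer"),
                function(el) {
                  element_enrichment(bs, annotations[[el]],
                                     annotations$background)$odds_ratio
                }, numeric(1))
  cp <- conservation_profile(bs, annotations$conservation, windows = 20L)
  chrM <- annotations$chrM %||% "chrM"
  frac_m <- mean(bs$calls$chrom == chrM)
  out <- c(or_exon = unname(ors["exon"]), or_intron = unname(ors["intron"]),
           or_promoter = unname(ors["promoter"]),
           or_insulator = unname(ors["insulator"]),
           or_enhancer = unname(ors["enhancer"]),
           phylop_positive = cp$profile$mean_positive[1],
           phylop_negative_abs = cp$profile$mean_negative_abs[1],
           chrM_fraction = frac_m)
  if (any(!is.finite(out)))
    warning("non-finite sample feature(s): ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Logistic age-group classifier on breakome features
#'
#' Maximum-likelihood logistic regression of an age-group label (e.g.
#' young <= 30 vs old >= 58) on sample feature vectors, with training-set
#' accuracy at probability threshold 0.5, ROC curve and AUC, and
#' McFadden's pseudo-R2 = 1 - lnL(model)/lnL(null). Perfect separation is
#' flagged rather than treated as an error.
#'
#' @param features matrix or data.frame, samples x features.
#' @param labels factor or binary vector (two classes; the second level is
#'   modelled as the positive class).
#' @param folds optional integer: evaluate accuracy/ROC/AUC on
#'   out-of-fold predicted probabilities from \code{folds}-fold
#'   cross-validation (seeded) instead of in-sample fitted probabilities.
#'   Coefficients and pseudo-R2 always come from the full fit.
#' @param seed fold-assignment seed (used only with \code{folds}).
#' @return object of class \code{ssb_age_classifier} with elements
#'   \code{fit} (the glm), \code{accuracy}, \code{auc}, \code{roc}
#'   (data.frame fpr/tpr), \code{pseudo_r2}, \code{separation_flagged}.
#' @export
fit_age_classifier <- function(features, labels, folds = NULL, seed = 1L) {
  df <- as.data.frame(features)
  y <- as.factor(labels)
  if (nlevels(y) != 2) stop("labels must have exactly two classes", call. = FALSE)
  df$.y <- y
  quiet_glm <- function(data) {
    withCallingHandlers(glm(.y ~ ., data = data, family = binomial()),
                        warning = function(cond) invokeRestart("muffleWarning"))
  }
  fit <- quiet_glm(df)
  sep <- any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) ||
    !fit$converged
  if (is.null(folds)) {
    prob <- predict(fit, type = "response")
  } else {
    set.seed(as.integer(seed))
    fold_of <- sample(rep_len(seq_len(folds), nrow(df)))
    prob <- numeric(nrow(df))
    for (f in seq_len(folds)) {
      hold <- fold_of == f
      fit_f <- quiet_glm(df[!hold, , drop = FALSE])
      prob[hold] <- predict(fit_f, newdata = df[hold, , drop = FALSE],
                            type = "response")
    }
  }
  pred <- levels(y)[1 + (prob > 0.5)]
  acc <- mean(pred == as.character(y))
  rc <- pROC::roc(response = y, predictor = prob, quiet = TRUE,
                  levels = levels(y), direction = "<")
  null_fit <- glm(.y ~ 1, data = df, family = binomial())
  pr2 <- 1 - as.numeric(logLik(fit)) / as.numeric(logLik(null_fit))
  structure(list(fit = fit, accuracy = acc, auc = as.numeric(rc$auc),
                 roc = data.frame(fpr = 1 - rc$specificities,
                                  tpr = rc$sensitivities),
                 pseudo_r2 = pr2, separation_flagged = sep,
                 labels = y),
            class = "ssb_age_classifier")
}

#' @export
print.ssb_age_classifier <- function(x, ...) {
  cat(sprintf("Logistic age classifier: accuracy %.1f%%, AUC %.3f, McFadden pseudo-R2 %.3f\n",
              100 * x$accuracy, x$auc, x$pseudo_r2))
  if (x$separation_flagged)
    cat("  note: (quasi-)complete separation; coefficients unstable\n")
  invisible(x)
}

#' @export
summary.ssb_age_classifier <- function(object, ...) {
  print(object)
  print(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
coef.ssb_age_classifier <- function(object, ...) coef(object$fit)

#' @export
predict.ssb_age_classifier <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit, type = "response")
  else predict(object$fit, newdata = as.data.frame(newdata), type = "response")
}

#' @export
plot.ssb_age_classifier <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Multiple linear regression of age on breakome features
#'
#' Least-squares fit of chronological age on the feature vector; reports
#' fitted ("breakome") ages, the Pearson correlation between fitted and
#' chronological age, and the overall model F-test p-value. Rank-deficient
#' designs are reported and fitted through the default pivoting.
#'
#' @param features matrix or data.frame, samples x features.
#' @param ages numeric chronological ages (>= 2 distinct values).
#' @return object of class \code{ssb_age_regressor}: \code{fit},
#'   \code{fitted_ages}, \code{pearson_r}, \code{p_value},
#'   \code{rank_deficient}.
#' @export
fit_age_regressor <- function(features, ages) {
  if (length(unique(ages)) < 2)
    stop("need at least 2 distinct ages", call. = FALSE)
  df <- as.data.frame(features)
  df$.age <- ages
  fit <- lm(.age ~ ., data = df)
  rd <- fit$rank < ncol(df)
  if (rd) warning("rank-deficient design; some coefficients aliased")
  r <- cor(fitted(fit), ages)
  fs <- summary(fit)$fstatistic
  p <- if (is.null(fs)) NA_real_ else
    unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  structure(list(fit = fit, fitted_ages = fitted(fit), pearson_r = r,
                 p_value = p, rank_deficient = rd, ages = ages),
            class = "ssb_age_regressor")
}

#' @export
print.ssb_age_regressor <- function(x, ...) {
  cat(sprintf("Linear breakome-age model: Pearson r = %.3f (fitted vs chronological), p = %.3g\n",
              x$pearson_r, x$p_value))
  invisible(x)
}

#' @export
summary.ssb_age_regressor <- function(object, ...) {
  print(object)
  print(summary(object$fit)$coefficients)
  invisible(object)
}

#' @export
coef.ssb_age_regressor <- function(object, ...) coef(object$fit)

#' @export
predict.ssb_age_regressor <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) fitted(object$fit)
  else predict(object$fit, newdata = as.data.frame(newdata))
}

#' @export
plot.ssb_age_regressor <- function(x, ...) {
  plot(x$ages, x$fitted_ages, xlab = "Chronological age",
       ylab = "Breakome age (fitted)",
       main = sprintf("r = %.3f", x$pearson_r), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
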