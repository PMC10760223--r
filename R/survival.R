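#' Residualize a gene on its upstream genes
#'
#' Applies the annihilator of the upstream design (with intercept) to the
#' gene's expression vector: the result is the part of the gene's
#' expression not explained by its upstream genes, orthogonal to every
#' upstream column.  With no upstream genes the vector is simply centered.
#' Collinear upstream columns are dropped with a warning.
#'
#' @param g Expression vector of the gene.
#' @param G Samples x upstream-genes matrix, or `NULL`.
#' @return Residual vector of the same length.
#' @export
residualize_on_upstream <- function(g, G = NULL) {
  if (is.null(G) || NCOL(G) == 0) return(g - mean(g))
  G <- as.matrix(G)
  X <- cbind(1, G)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("rank-deficient upstream design; dropping collinear column(s)")
  }
  as.numeric(qr.resid(qx, g))
}

#' Cox proportional-hazards fit for one sub-network and arm
#'
#' Implements the network-residualized hazard specification
#' `h(t) = h0(t) exp(gamma * Gtilde + beta * G + theta * Z + delta * T)`:
#' every sub-network gene enters through its upstream-residualized
#' expression (so its coefficient is the gene's effect on overall survival
#' *not* attributable to its upstream, confounding genes), the raw upstream
#' genes enter as adjustment columns, plus clinical covariates and enriched
#' cell fractions.  Exactly collinear columns (e.g. a root gene whose
#' residual is just its centered expression, duplicated by a raw upstream
#' column) are aliased by the fitter, keeping the residualized copy.  Ties
#' use the Efron approximation.
#'
#' @param surv Data frame `time`, `event` aligned with the expression rows.
#' @param subnetwork A `subnetwork` object from [extract_subnetworks()].
#' @param expression Samples x genes matrix (log2, adjusted or not — the
#'   scale the hazard is modelled on).
#' @param covariates Optional covariate data frame (arm column ignored).
#' @param cell_fractions Optional samples x cell-type matrix.
#' @param arm Optional arm label vector; with `arm_label` set, rows are
#'   restricted to that arm.
#' @param arm_label Which arm to fit (default: all rows).
#' @param mode `"joint"` fits one model for the whole sub-network;
#'   `"per_gene"` fits one model per gene (its residual + its raw upstream
#'   + covariates).
#' @param min_events Minimum number of events required.
#' @return Data frame of class `cox_subnetwork_fit`: one row per gene with
#'   `arm`, `gene`, `hr`, `log_hr`, `log_hr_se`, `p`, `upstream_used`,
#'   `converged`, `n`, `n_events`.
#' @export
fit_cox_subnetwork <- function(surv, subnetwork, expression,
                               covariates = NULL, cell_fractions = NULL,
                               arm = NULL, arm_label = NULL,
                               mode = c("joint", "per_gene"),
                               min_events = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(subnetwork, "subnetwork"))
  keep <- rep(TRUE, nrow(expression))
  if (!is.null(arm_label)) {
    if (is.null(arm)) stop("`arm_label` given without `arm` vector")
    keep <- arm == arm_label
  }
  time <- surv$time[keep]
  event <- surv$event[keep]
  if (any(time <= 0)) stop("survival times must be positive")
  if (sum(event) < min_events) {
    stop(sprintf("only %d events in arm; need >= %d", sum(event), min_events))
  }
  X <- expression[keep, , drop = FALSE]
  genes <- subnetwork$members
  gtilde <- vapply(genes, function(g) {
    up <- intersect(subnetwork$upstream[[g]], colnames(X))
    residualize_on_upstream(X[, g], if (length(up)) X[, up, drop = FALSE])
  }, numeric(sum(keep)))
  colnames(gtilde) <- paste0("res_", genes)
  upstream_all <- sort(unique(unlist(subnetwork$upstream)))
  upstream_all <- intersect(upstream_all, colnames(X))
  Zd <- design_from_df(if (is.null(covariates)) NULL else
    covariates[keep, setdiff(names(covariates), c("sample", "arm")),
               drop = FALSE])
  Td <- if (is.null(cell_fractions)) NULL else
    cell_fractions[keep, , drop = FALSE]

  fit_one <- function(design, want_genes) {
    df <- as.data.frame(design)
    names(df) <- make.names(colnames(design), unique = TRUE)
    df$.time <- time
    df$.event <- event
    conv <- TRUE
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(.time, .event) ~ . - .time - .event,
                      data = df, ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|singular|loglik", conditionMessage(w))) {
          conv <<- FALSE
        }
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    out <- lapply(want_genes, function(g) {
      rn <- make.names(paste0("res_", g))
      if (!(rn %in% rownames(sm)) || is.na(sm[rn, "coef"])) {
        return(data.frame(gene = g, hr = NA_real_, log_hr = NA_real_,
                          log_hr_se = NA_real_, p = NA_real_,
                          converged = FALSE))
      }
      data.frame(gene = g, hr = sm[rn, "exp(coef)"], log_hr = sm[rn, "coef"],
                 log_hr_se = sm[rn, "se(coef)"],
                 p = sm[rn, "Pr(>|z|)"], converged = conv)
    })
    do.call(rbind, out)
  }

  bind_design <- function(...) {
    parts <- Filter(function(p) !is.null(p) && NCOL(p) > 0, list(...))
    as.matrix(do.call(cbind, lapply(parts, as.data.frame)))
  }
  raw_cols <- function(gs) {
    if (!length(gs)) return(NULL)
    stats::setNames(as.data.frame(X[, gs, drop = FALSE]),
                    paste0("raw_", gs))
  }
  res <- if (mode == "joint") {
    fit_one(bind_design(gtilde, raw_cols(upstream_all), Zd, Td), genes)
  } else {
    do.call(rbind, lapply(genes, function(g) {
      up <- intersect(subnetwork$upstream[[g]], colnames(X))
      fit_one(bind_design(gtilde[, paste0("res_", g), drop = FALSE],
                          raw_cols(up), Zd, Td), g)
    }))
  }
  res$arm <- arm_label %||% "all"
  res$subnetwork <- subnetwork$anchor
  res$upstream_used <- vapply(res$gene, function(g)
    paste(subnetwork$upstream[[g]], collapse = ","), character(1))
  res$n <- sum(keep)
  res$n_events <- sum(event)
  rownames(res) <- NULL
  class(res) <- c("cox_subnetwork_fit", "data.frame")
  res
}

#' Define a survival gene signature from Cox fits
#'
#' The signature of a sub-network in one arm is the set of genes with a
#' significant effect on overall survival (p < `p_max`, default 0.1) in the
#' residualized Cox fit, each carrying a beneficial direction:
#' `beneficial-high` when its hazard ratio is below 1 (higher expression
#' prolongs survival), `beneficial-low` otherwise.  Empty signatures are
#' allowed.
#'
#' @param fits A `cox_subnetwork_fit` data frame.
#' @param p_max Significance threshold on the per-gene Wald p-value.
#' @return Object of class `signature`: `arm`, `subnetwork`, `genes`
#'   (gene, hr, p, direction).
#' @export
define_signature <- function(fits, p_max = 0.1) {
  keep <- !is.na(fits$p) & fits$p < p_max & fits$converged
  genes <- fits[keep, c("gene", "hr", "p"), drop = FALSE]
  genes$direction <- ifelse(genes$hr < 1, "beneficial-high", "beneficial-low")
  rownames(genes) <- NULL
  structure(list(arm = unique(fits$arm), subnetwork = unique(fits$subnetwork),
                 genes = genes),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature (%s, sub-network %s): %d gene(s)\n",
              paste(x$arm, collapse = "/"),
              paste(x$subnetwork, collapse = "/"), nrow(x$genes)))
  if (nrow(x$genes)) print(x$genes)
  invisible(x)
}

#' Dichotomize expression at the third quartile
#'
#' Splits one arm's expression of a gene at its 75th percentile (linear
#' interpolation).  For a `beneficial-high` gene a sample is in the
#' beneficial state when expression strictly exceeds Q3; for
#' `beneficial-low`, when it does not.
#'
#' @param x Expression vector for one gene within one arm.
#' @param direction `"beneficial-high"` or `"beneficial-low"`.
#' @param quantile_type Quantile convention.
#' @return Logical vector: `TRUE` = beneficial state.
#' @export
dichotomize_third_quartile <- function(x, direction = c("beneficial-high",
                                                        "beneficial-low"),
                                       quantile_type = 7) {
  direction <- match.arg(direction)
  if (length(x) < 4) stop("need at least 4 samples to take a third quartile")
  q3 <- stats::quantile(x, 0.75, type = quantile_type, names = FALSE)
  if (stats::sd(x) == 0) warning("constant expression; single state")
  high <- x > q3
  if (direction == "beneficial-high") high else !high
}

#' Stratify patients by a gene signature
#'
#' A patient is `beneficial` when in the beneficial state on *every*
#' signature gene, `non-beneficial` when in the non-beneficial state on
#' every gene, and `mixed` otherwise.  The three groups partition the
#' samples.
#'
#' @param signature A [define_signature()] object (non-empty).
#' @param expression Samples x genes matrix for the arm being stratified.
#' @param quantile_type Quantile convention for the per-gene Q3 split.
#' @return Factor with levels beneficial / mixed / non-beneficial.
#' @export
stratify_patients <- function(signature, expression, quantile_type = 7) {
  stopifnot(inherits(signature, "signature"))
  if (!nrow(signature$genes)) stop("signature is empty")
  states <- vapply(seq_len(nrow(signature$genes)), function(i) {
    g <- signature$genes$gene[i]
    dichotomize_third_quartile(expression[, g],
                               signature$genes$direction[i],
                               quantile_type)
  }, logical(nrow(expression)))
  states <- matrix(states, nrow = nrow(expression))
  grp <- ifelse(rowSums(states) == ncol(states), "beneficial",
                ifelse(rowSums(states) == 0, "non-beneficial", "mixed"))
  factor(grp, levels = c("beneficial", "mixed", "non-beneficial"))
}

#' Kaplan-Meier curves and median survival per group
#'
#' Product-limit estimates per group via [survival::survfit()]; the median
#' is re-derived as the smallest time with `S(t) <= 0.5` (undefined, `NA`,
#' when the curve never reaches 0.5).  Every returned curve is checked to
#' start at `S(0) = 1` and be non-increasing.
#'
#' @param time,event Survival outcome vectors.
#' @param groups Group labels (factor or character); empty groups are
#'   skipped with a warning.
#' @return List `curves` (per group: data frame `time`, `surv`, including
#'   the `(0, 1)` point), `median_os` (named vector).
#' @export
km_estimate <- function(time, event, groups = NULL) {
  if (any(time <= 0)) stop("survival times must be positive")
  groups <- if (is.null(groups)) factor(rep("all", length(time)))
            else factor(groups)
  if (any(table(groups) == 0)) {
    warning("empty group(s) skipped: ",
            paste(levels(groups)[table(groups) == 0], collapse = ", "))
    groups <- droplevels(groups)
  }
  curves <- list()
  med <- stats::setNames(rep(NA_real_, nlevels(groups)), levels(groups))
  for (gl in levels(groups)) {
    sel <- groups == gl
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    cv <- data.frame(time = c(0, sf$time), surv = c(1, sf$surv))
    if (any(diff(cv$surv) > 1e-12) || cv$surv[1] != 1) {
      stop("Kaplan-Meier curve violates monotonicity")  # defensive
    }
    curves[[gl]] <- cv
    hit <- cv$time[cv$surv <= 0.5]
    if (length(hit)) med[gl] <- min(hit)
  }
  list(curves = curves, median_os = med)
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank chi-square via [survival::survdiff()].
#'
#' @param time,event Survival outcome vectors.
#' @param groups Group labels; at least 2 non-empty groups required.
#' @return List `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  df <- length(sd$n) - 1
  list(statistic = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Wilcoxon rank-sum comparison of follow-up times
#'
#' Two-sided rank-sum test used to replicate a stratification on an
#' external cohort where only follow-up times are available: exact when the
#' combined sample size is at most 20 and no ties are present, otherwise
#' the normal approximation with tie correction.
#'
#' @param x,y Follow-up times of the two groups (each of length >= 3).
#' @return List `statistic` (W), `p`.
#' @export
wilcoxon_replication <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) stop("each group needs >= 3 values")
  if (length(unique(c(x, y))) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  exact <- (length(x) + length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}
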