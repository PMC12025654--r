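#' Analysis configuration
#'
#' @param alpha significance level for flagging terms (raw p-values; no
#'   multiple-testing correction by default, mirroring exploratory
#'   single-test reporting -- an optional Holm adjustment is available).
#' @param weights `"fence"` (percentile-fence geometric-mean weights,
#'   default) or `"none"` (unit weights).
#' @param va_outcome `"change"` (3-year minus baseline logMAR, baseline
#'   entered as confounder; default) or `"final"` (3-year logMAR adjusted
#'   for baseline).
#' @param count_model `"linear"` (weighted linear regression of the
#'   injection count, default) or `"poisson"` (weighted Poisson log-linear
#'   fit via [stats::glm]); the linear model is the default because the
#'   count outcome is analyzed as an interval-scaled variable.
#' @param holm apply a Holm adjustment across the vascular-parameter
#'   injection models.
#' @return list of class `mnv_analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05,
                            weights = c("fence", "none"),
                            va_outcome = c("change", "final"),
                            count_model = c("linear", "poisson"),
                            holm = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  structure(
    list(
      alpha = alpha, weights = match.arg(weights),
      va_outcome = match.arg(va_outcome),
      count_model = match.arg(count_model), holm = isTRUE(holm)
    ),
    class = "mnv_analysis_config"
  )
}

#' Relate MNV vascular parameters to treatment demand and visual acuity
#'
#' Fits one weighted regression per (vascular parameter, outcome) pair:
#' each of area, sumL, FD, and flow density against (a) the 3-year
#' intravitreal injection count and (b) the visual-acuity outcome (change
#' score by default, with baseline logMAR as confounder), plus two models
#' entering MNV type as a pair of indicator terms with a joint F-test.
#' Observation weights are the geometric mean of the percentile-fence
#' weights of the continuous variables involved in each model
#' ([fence_thresholds()], [outlier_weight()], [combine_weights()]);
#' categorical type indicators carry no fence. Models that cannot be fit
#' are reported as failed entries, never dropped silently. The report is
#' invariant to the row order of the cohort.
#'
#' @param cohort per-eye cohort table (schema of [read_cohort()]).
#' @param config `mnv_analysis_config`.
#' @return object of class `mnv_analysis_report`: list with `table` (flat
#'   data.frame: `model`, `outcome`, `term`, `estimate`, `se`,
#'   `statistic`, `p_value`, `significant`), `models` (per-model details:
#'   fit, fences, weights, `joint_p` for the type models), `alpha`,
#'   `config`.
#' @examples
#' report <- analyze_cohort(generate_cohort(default_cohort_params(), seed = 7))
#' subset(report$table, term != "(Intercept)")
#' @export
analyze_cohort <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "mnv_analysis_config"))
  cohort <- validate_cohort(cohort)
  params <- c("area_mm2", "suml_mm", "fd", "flow_density_pct")

  va_change <- cohort$bcva_3y_logmar - cohort$bcva_baseline_logmar
  va_y <- if (config$va_outcome == "change") va_change else
    cohort$bcva_3y_logmar
  va_name <- if (config$va_outcome == "change") "va_change_logmar" else
    "bcva_3y_logmar"
  work <- cohort
  work[[va_name]] <- va_y

  models <- list()

  fit_one <- function(id, outcome, iv_cols, y, confounder_col = NULL,
                      joint_terms = NULL) {
    wvars <- c(outcome, iv_cols[iv_cols %in% names(cohort_numeric_vars())],
               confounder_col)
    wvars <- intersect(wvars, names(work))
    fw <- if (config$weights == "fence") fence_weights(work, wvars) else
      list(weights = rep(1, nrow(work)), fences = list())
    X <- as.matrix(work[, iv_cols, drop = FALSE])
    conf <- if (is.null(confounder_col)) NULL else {
      cm <- as.matrix(work[, confounder_col, drop = FALSE])
      cm
    }
    entry <- list(
      outcome = outcome, iv = iv_cols, confounder = confounder_col,
      fences = fw$fences, weights = fw$weights, failed = FALSE,
      error = NULL, joint_p = NA_real_
    )
    fit <- tryCatch(
      weighted_linear_fit(y, X, confounder = conf, weights = fw$weights),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      entry$failed <- TRUE
      entry$error <- conditionMessage(fit)
      return(entry)
    }
    entry$fit <- fit
    entry$terms <- data.frame(
      term = fit$terms, estimate = fit$coefficients, se = fit$se,
      statistic = fit$statistic, p_value = fit$p_value,
      stringsAsFactors = FALSE, row.names = NULL
    )
    if (!is.null(joint_terms)) {
      reduced_X <- if (is.null(conf)) {
        matrix(numeric(nrow(work)), ncol = 1L,
               dimnames = list(NULL, "null"))
      } else conf
      reduced <- tryCatch(
        if (is.null(conf)) {
          weighted_linear_fit(y, X[, 0, drop = FALSE], confounder = NULL,
                              weights = fw$weights)
        } else {
          weighted_linear_fit(y, conf, weights = fw$weights)
        },
        error = function(e) e
      )
      if (!inherits(reduced, "error")) {
        entry$joint_p <- joint_f_test(fit, reduced)$p_value
      }
    }
    entry
  }

  # vascular parameter vs injection count
  for (p in params) {
    id <- paste0(p, "_vs_ivi")
    if (config$count_model == "poisson") {
      models[[id]] <- fit_poisson_model(work, p, config)
    } else {
      models[[id]] <- fit_one(id, "ivi_count_3y", p,
                              work$ivi_count_3y)
    }
  }
  # vascular parameter vs visual acuity (baseline as confounder)
  for (p in params) {
    id <- paste0(p, "_vs_va")
    models[[paste0(p, "_vs_va")]] <- fit_one(
      id, va_name, p, va_y, confounder_col = "bcva_baseline_logmar"
    )
  }
  # MNV type (two indicators, joint test)
  type2 <- as.numeric(work$mnv_type == 2L)
  type3 <- as.numeric(work$mnv_type == 3L)
  tX <- cbind(mnv_type2 = type2, mnv_type3 = type3)
  work$mnv_type2 <- type2; work$mnv_type3 <- type3
  models[["mnv_type_vs_ivi"]] <- fit_one(
    "mnv_type_vs_ivi", "ivi_count_3y", c("mnv_type2", "mnv_type3"),
    work$ivi_count_3y, joint_terms = c("mnv_type2", "mnv_type3")
  )
  models[["mnv_type_vs_va"]] <- fit_one(
    "mnv_type_vs_va", va_name, c("mnv_type2", "mnv_type3"), va_y,
    confounder_col = "bcva_baseline_logmar",
    joint_terms = c("mnv_type2", "mnv_type3")
  )

  tab <- do.call(rbind, lapply(names(models), function(id) {
    m <- models[[id]]
    if (m$failed || is.null(m$terms)) {
      return(data.frame(
        model = id, outcome = m$outcome, term = NA_character_,
        estimate = NA_real_, se = NA_real_, statistic = NA_real_,
        p_value = NA_real_, stringsAsFactors = FALSE
      ))
    }
    cbind(model = id, outcome = m$outcome, m$terms,
          stringsAsFactors = FALSE)
  }))
  if (config$holm) {
    ivi_rows <- tab$model %in% paste0(params, "_vs_ivi") &
      tab$term %in% params
    tab$p_value[ivi_rows] <- stats::p.adjust(tab$p_value[ivi_rows],
                                             method = "holm")
  }
  tab$significant <- !is.na(tab$p_value) & tab$p_value < config$alpha &
    tab$term != "(Intercept)"
  rownames(tab) <- NULL

  structure(
    list(table = tab, models = models, alpha = config$alpha,
         config = unclass(config), n_eyes = nrow(cohort)),
    class = "mnv_analysis_report"
  )
}

cohort_numeric_vars <- function() {
  c(area_mm2 = "numeric", suml_mm = "numeric", fd = "numeric",
    flow_density_pct = "numeric", bcva_baseline_logmar = "numeric",
    bcva_3y_logmar = "numeric", va_change_logmar = "numeric",
    ivi_count_3y = "numeric")
}

# optional count-model branch: weighted Poisson log-linear fit
fit_poisson_model <- function(work, p, config) {
  wvars <- c("ivi_count_3y", p)
  fw <- if (config$weights == "fence") fence_weights(work, wvars) else
    list(weights = rep(1, nrow(work)), fences = list())
  df <- data.frame(y = work$ivi_count_3y, x = work[[p]])
  fit <- tryCatch(
    stats::glm(y ~ x, family = stats::poisson(), data = df,
               weights = fw$weights),
    error = function(e) e
  )
  entry <- list(outcome = "ivi_count_3y", iv = p, confounder = NULL,
                fences = fw$fences, weights = fw$weights, failed = FALSE,
                error = NULL, joint_p = NA_real_)
  if (inherits(fit, "error")) {
    entry$failed <- TRUE; entry$error <- conditionMessage(fit)
    return(entry)
  }
  sm <- summary(fit)$coefficients
  entry$terms <- data.frame(
    term = c("(Intercept)", p), estimate = sm[, 1L], se = sm[, 2L],
    statistic = sm[, 3L], p_value = sm[, 4L],
    stringsAsFactors = FALSE, row.names = NULL
  )
  entry
}

#' @export
print.mnv_analysis_report <- function(x, ...) {
  cat(sprintf("MNV cohort analysis (%d eyes, alpha = %g, weights = %s)\n",
              x$n_eyes, x$alpha, x$config$weights))
  show <- x$table[is.na(x$table$term) | x$table$term != "(Intercept)", ]
  show$p_value <- signif(show$p_value, 3L)
  show$estimate <- signif(show$estimate, 4L)
  print(show[, c("model", "term", "estimate", "p_value", "significant")],
        row.names = FALSE)
  jp <- vapply(x$models, function(m) m$joint_p, numeric(1L))
  jp <- jp[!is.na(jp)]
  if (length(jp)) {
    cat("joint tests:\n")
    for (nm in names(jp)) cat(sprintf("  %s: p = %.4g\n", nm, jp[nm]))
  }
  invisible(x)
}
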