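#' Filter a results table for analysis
#'
#' Applies the exclusion rules used before modelling: practice-phase trials
#' are not analysed, timed-out trials are excluded, failed trials are
#' excluded, and trials with targeting error greater than `max_error`
#' (20 m) are discounted as mechanical or attentional errors. Idempotent.
#'
#' @param table A results table.
#' @param max_error Error exclusion threshold, m.
#' @return The filtered table; attribute `filter_counts` reports how many
#'   rows each rule removed and the overall fraction dropped.
#' @export
filter_trials <- function(table, max_error = 20) {
  n0 <- nrow(table)
  is_practice <- if ("phase" %in% names(table))
    table$phase == "practice" else rep(FALSE, n0)
  is_failed <- if ("failed" %in% names(table))
    isTRUE_vec(table$failed) else rep(FALSE, n0)
  is_timeout <- isTRUE_vec(table$timed_out)
  err <- table$targeting_error_m
  is_far <- !is.na(err) & err > max_error
  keep <- !is_practice & !is_failed & !is_timeout & !is_far
  out <- table[keep, , drop = FALSE]
  attr(out, "filter_counts") <- list(
    input = n0,
    practice = sum(is_practice),
    failed = sum(is_failed & !is_practice),
    timed_out = sum(is_timeout & !is_practice & !is_failed),
    over_max_error = sum(is_far & !is_practice & !is_failed & !is_timeout),
    retained = nrow(out),
    fraction_dropped_by_error_rule =
      sum(is_far & !is_practice & !is_failed & !is_timeout) /
      max(1L, n0 - sum(is_practice)))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Natural-log flock size
#'
#' Targeting error, hunting time and approach speed are approximately
#' log-normal in flock size, so all models use ln(flock size).
#'
#' @param table A results table with `flock_size >= 1`.
#' @return The table with an added `log_size` column.
#' @export
transform_size <- function(table) {
  if (any(table$flock_size < 1))
    stop("invalid flock size: must be >= 1", call. = FALSE)
  table$log_size <- log(table$flock_size)
  table
}

#' Prepare a results table for modelling
#'
#' Filter (practice, timeouts, > 20 m errors), then normalize targeting
#' error against each participant's singleton baseline, then add the
#' log-size transform — in that order.
#'
#' @inheritParams filter_trials
#' @return The analysis-ready table (keeps the `filter_counts` attribute).
#' @export
prepare_results <- function(table, max_error = 20) {
  out <- filter_trials(table, max_error)
  counts <- attr(out, "filter_counts")
  out <- normalize_error(out)
  out <- transform_size(out)
  attr(out, "filter_counts") <- counts
  out
}

#' Fit a linear mixed model for one response
#'
#' Maximum-likelihood fit (not REML, so deviances of nested fits are
#' comparable) of a response against orthogonal-polynomial terms in
#' ln(flock size) and in density (numeric NND), optionally with their
#' interaction, with a per-participant random intercept.
#'
#' @param response Response column name.
#' @param table Analysis-ready table (see [prepare_results()]).
#' @param size_degree Polynomial degree for ln(size): 0 (omit), 1 or 2.
#' @param density_degree Polynomial degree for density: 0 (omit), 1 or 2.
#' @param interaction Include the size x density interaction terms?
#' @return An object of class `mixed_fit`: list with the `lme4` model,
#'   `deviance`, `n_par` (total parameter count), `nobs` and the formula.
#' @export
fit_mixed <- function(response, table, size_degree = 2L,
                      density_degree = 2L, interaction = TRUE) {
  stopifnot(response %in% names(table), "log_size" %in% names(table))
  if (length(unique(table$participant)) < 2L)
    stop("mixed model needs >= 2 participants", call. = FALSE)
  terms <- character()
  if (size_degree > 0) {
    if (length(unique(table$log_size)) <= size_degree)
      stop("not enough distinct flock sizes for the requested degree",
           call. = FALSE)
    terms <- c(terms, sprintf("poly(log_size, %d)", size_degree))
  }
  if (density_degree > 0) {
    if (length(unique(table$density)) <= density_degree)
      stop("not enough distinct densities for the requested degree",
           call. = FALSE)
    terms <- c(terms, sprintf("poly(density, %d)", density_degree))
  }
  fixed <- if (length(terms) == 0L) "1"
  else paste(terms, collapse = if (interaction && length(terms) == 2L)
    " * " else " + ")
  fml <- stats::as.formula(paste0("`", response, "` ~ ", fixed,
                                  " + (1 | participant)"))
  model <- tryCatch(
    lme4::lmer(fml, data = table, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular =
                                             "ignore")),
    error = function(e) stop("mixed-model fit failed: ", conditionMessage(e),
                             call. = FALSE))
  ll <- stats::logLik(model)
  out <- list(model = model, deviance = as.numeric(-2 * ll),
              n_par = attr(ll, "df"), nobs = stats::nobs(model),
              formula = fml, response = response,
              coefficients = lme4::fixef(model))
  class(out) <- "mixed_fit"
  out
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit>", deparse(x$formula), "\n  deviance", round(x$deviance, 2),
      "| parameters", x$n_par, "| n", x$nobs, "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested mixed models
#'
#' The change in deviance between the simpler and the more complex
#' maximum-likelihood fit is referred to a chi-squared distribution with
#' degrees of freedom equal to the difference in parameter count.
#'
#' @param simple,complex `mixed_fit` objects fitted to the same data, the
#'   first nested in the second.
#' @return A `model_comparison`: list with `chi_square`, `df`, `p_value` and
#'   the two deviances.
#' @export
lrt <- function(simple, complex) {
  stopifnot(inherits(simple, "mixed_fit"), inherits(complex, "mixed_fit"))
  if (simple$nobs != complex$nobs)
    stop("comparison refused: models were fitted to different row counts",
         call. = FALSE)
  if (simple$n_par > complex$n_par)
    stop("comparison refused: 'simple' has more parameters than 'complex'",
         call. = FALSE)
  chi2 <- max(0, simple$deviance - complex$deviance)
  df <- complex$n_par - simple$n_par
  p <- if (df == 0L) as.numeric(chi2 <= 0) else
    stats::pchisq(chi2, df = df, lower.tail = FALSE)
  out <- list(chi_square = chi2, df = df, p_value = p,
              deviance_simple = simple$deviance,
              deviance_complex = complex$deviance)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("chi2 = %.3f, d.f. = %d, p = %.4g\n", x$chi_square, x$df,
              x$p_value))
  invisible(x)
}

#' Full model-comparison analysis
#'
#' Runs the study's decision tree for each response: (1) decide whether
#' ln(flock size) needs a quadratic polynomial or a linear term (LRT of the
#' full interaction models), (2) likewise for density, (3) test the size x
#' density interaction; if the interaction is significant, test the effect of
#' flock size separately within each density setting, otherwise test the two
#' main effects by dropping each from the additive model.
#'
#' @param table Analysis-ready table from [prepare_results()].
#' @param responses Named character vector mapping report labels to response
#'   columns.
#' @param alpha Significance threshold used by the tree's decisions.
#' @return A list of class `confusion_report`; one element per response with
#'   the chosen polynomial degrees and every `model_comparison`.
#' @export
run_paper_analysis <- function(table,
                               responses = c(
                                 targeting_error = "targeting_error_m_norm",
                                 hunting_time = "hunting_time_s",
                                 movement_speed = "movement_speed",
                                 approach_speed = "approach_speed"),
                               alpha = 0.05) {
  responses <- responses[unname(responses) %in% names(table)]
  # the polynomial bases cannot exceed the number of distinct levels - 1
  sdeg_hi <- min(2L, length(unique(table$flock_size)) - 1L)
  ddeg_hi <- min(2L, length(unique(table$density)) - 1L)
  if (sdeg_hi < 1L)
    stop("analysis needs at least two distinct flock sizes", call. = FALSE)
  report <- lapply(names(responses), function(label) {
    resp <- responses[[label]]
    res <- list(response = resp)

    sdeg <- sdeg_hi
    if (sdeg_hi == 2L) {
      m_s2 <- fit_mixed(resp, table, 2L, ddeg_hi, ddeg_hi > 0L)
      m_s1 <- fit_mixed(resp, table, 1L, ddeg_hi, ddeg_hi > 0L)
      res$size_poly_test <- lrt(m_s1, m_s2)
      sdeg <- if (res$size_poly_test$p_value < alpha) 2L else 1L
    }

    ddeg <- ddeg_hi
    if (ddeg_hi == 2L) {
      m_d2 <- fit_mixed(resp, table, sdeg, 2L, TRUE)
      m_d1 <- fit_mixed(resp, table, sdeg, 1L, TRUE)
      res$density_poly_test <- lrt(m_d1, m_d2)
      ddeg <- if (res$density_poly_test$p_value < alpha) 2L else 1L
    }

    res$size_degree <- sdeg
    res$density_degree <- ddeg
    if (ddeg == 0L) {   # single density setting: size effect only
      m1 <- fit_mixed(resp, table, sdeg, 0L, FALSE)
      m0 <- fit_mixed(resp, table, 0L, 0L, FALSE)
      res$size_main_test <- lrt(m0, m1)
      return(res)
    }

    m_int <- fit_mixed(resp, table, sdeg, ddeg, TRUE)
    m_add <- fit_mixed(resp, table, sdeg, ddeg, FALSE)
    res$interaction_test <- lrt(m_add, m_int)

    if (res$interaction_test$p_value < alpha) {
      # effect of flock size within each density setting
      res$size_by_density <- lapply(sort(unique(table$density)),
                                    function(dv) {
        sub <- table[table$density == dv, , drop = FALSE]
        m1 <- fit_mixed(resp, sub, sdeg, 0L, FALSE)
        m0 <- fit_mixed(resp, sub, 0L, 0L, FALSE)
        c(list(density = dv), unclass(lrt(m0, m1)))
      })
    } else {
      m_nosize <- fit_mixed(resp, table, 0L, ddeg, FALSE)
      m_nodens <- fit_mixed(resp, table, sdeg, 0L, FALSE)
      res$size_main_test <- lrt(m_nosize, m_add)
      res$density_main_test <- lrt(m_nodens, m_add)
    }
    res
  })
  names(report) <- names(responses)
  attr(report, "alpha") <- alpha
  attr(report, "filter_counts") <- attr(table, "filter_counts")
  class(report) <- "confusion_report"
  report
}

#' @export
print.confusion_report <- function(x, ...) {
  for (nm in names(x)) {
    r <- x[[nm]]
    cat("==", nm, sprintf("(size degree %d, density degree %d)\n",
                          r$size_degree, r$density_degree))
    fmt <- function(label, cmp) {
      if (is.null(cmp)) return(invisible())
      cat(sprintf("  %-28s chi2 = %7.3f, d.f. = %d, p = %.4g\n", label,
                  cmp$chi_square, cmp$df, cmp$p_value))
    }
    fmt("size quadratic vs linear:", r$size_poly_test)
    fmt("density quadratic vs linear:", r$density_poly_test)
    fmt("size x density interaction:", r$interaction_test)
    if (!is.null(r$size_by_density)) {
      for (sb in r$size_by_density)
        fmt(sprintf("size effect at NND %.1f m:", sb$density), sb)
    } else {
      fmt("size main effect:", r$size_main_test)
      fmt("density main effect:", r$density_main_test)
    }
  }
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report A `confusion_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- lapply(report, function(r) {
    r <- rapply(r, function(z) z, how = "replace")
    lapply(r, function(el) if (inherits(el, "model_comparison"))
      unclass(el) else el)
  })
  out$filter_counts <- attr(report, "filter_counts")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Within-subject confidence intervals
#'
#' Cousineau-Morey 95% intervals for condition means in a repeated-measures
#' table (descriptive, for plotting only: each participant's data are
#' centred on the participant mean, and the interval width is corrected by
#' sqrt(C / (C - 1)) for C conditions).
#'
#' @param table Results table.
#' @param value Response column name.
#' @param by Character vector of condition columns.
#' @return A data.frame of condition means with `lower`/`upper` bounds.
#' @export
within_subject_ci <- function(table, value = "targeting_error_m",
                              by = c("flock_size", "density")) {
  v <- table[[value]]
  pm <- tapply(v, table$participant, mean, na.rm = TRUE)
  centred <- v - unname(pm[as.character(table$participant)]) +
    mean(v, na.rm = TRUE)
  cond <- interaction(table[by], drop = TRUE)
  C <- nlevels(cond)
  corr <- sqrt(C / max(1L, C - 1L))
  agg <- do.call(rbind, lapply(levels(cond), function(lv) {
    x <- centred[cond == lv]
    x <- x[is.finite(x)]
    se <- stats::sd(x) / sqrt(length(x)) * corr
    half <- stats::qt(0.975, df = max(1L, length(x) - 1L)) * se
    data.frame(condition = lv, mean = mean(x), lower = mean(x) - half,
               upper = mean(x) + half, n = length(x))
  }))
  agg
}

#' Read a participant-data text file
#'
#' Tolerant reader for externally supplied long-format trial tables: sniffs
#' the delimiter (comma, semicolon, tab or whitespace) and maps column names
#' onto the canonical schema by fuzzy matching. Fails with a schema report
#' listing the columns found when required ones are missing.
#'
#' @param path Text file with a header row.
#' @return A `results_table` data.frame.
#' @export
read_participant_data <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delims <- c("," = ",", ";" = ";", "\t" = "\t", " " = "")
  counts <- vapply(names(delims)[1:3], function(d)
    lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
    integer(1))
  delim <- if (max(counts) == 0L) "" else names(which.max(counts))
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, comment.char = "")
  canon <- list(
    participant = c("participant", "subject", "subj", "id", "ppt"),
    flock_size = c("flock_size", "flocksize", "size", "number", "n_birds",
                   "groupsize"),
    density = c("density", "nnd", "flock_density"),
    targeting_error_m = c("targeting_error_m", "targeting_error", "error",
                          "targetingerror", "clickerror"),
    hunting_time_s = c("hunting_time_s", "hunting_time", "huntingtime",
                       "time", "rt"),
    movement_speed = c("movement_speed", "movementspeed", "speed"),
    approach_speed = c("approach_speed", "approachspeed"),
    timed_out = c("timed_out", "timeout", "timedout"),
    phase = c("phase", "period", "practice"))
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(tab))))
  mapped <- names(tab)
  for (target in names(canon)) {
    hit <- which(nm %in% gsub("[^a-z0-9]", "", canon[[target]]))
    if (length(hit) >= 1L) mapped[hit[1L]] <- target
  }
  names(tab) <- mapped
  required <- c("participant", "flock_size", "targeting_error_m")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("schema error: could not identify column(s) ",
         paste(missing, collapse = ", "), "; file has columns: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  if (!"timed_out" %in% names(tab)) tab$timed_out <- FALSE
  if (!"phase" %in% names(tab)) tab$phase <- "experimental"
  if ("density" %in% names(tab) && is.character(tab$density))
    tab$density <- resolve_density(tab$density)
  class(tab) <- c("results_table", class(tab))
  tab
}
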