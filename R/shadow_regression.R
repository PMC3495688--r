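#' Fit a shadow regression and estimate sequencing error rates
#'
#' The main estimator. Selects the `top_k` most frequent reads, computes each
#' one's shadow profile with the whole top-k set excluded from shadow counts
#' (high-frequency reads are regarded as error free), robustly fits
#' s_t = alpha + beta * n_t over the (count, shadow-count) points, and
#' transforms the slope into the per-read error rate beta / (1 + beta).
#' Optionally the same regression is run per position on the
#' position-stratified shadow counts, giving per-base error rates.
#'
#' @param x input reads: a `read_count_table`, a named count vector, or a path
#'   to a FASTQ(.gz) or two-column tag-count file.
#' @param error_type `"substitution"` (default), `"insertion"`, `"deletion"`,
#'   or `"all"` (the three types estimated separately and summed).
#' @param top_k number of high-frequency reads used as regression points.
#' @param max_dist neighborhood radius in edits, 1 or 2.
#' @param per_position also estimate position-specific error rates.
#' @param indel_mask number of positions masked (reported `NA`) at each read
#'   end in per-position indel estimates, where shifted genuine reads bias the
#'   shadow counts.
#' @param se_method `"delta"` (analytic, default) or `"bootstrap"` (resample
#'   the regression points).
#' @param boot_reps bootstrap replicates when `se_method = "bootstrap"`.
#' @param adequacy_warn warn when the coverage-adequacy diagnostic fails
#'   (estimation proceeds regardless; coverage is guidance, not a gate).
#' @return An object of class `shadow_regression` with fields `error_rate`,
#'   `se`, `fit` (the [fit_robust_line()] result), `points` (data frame of
#'   read, n, s), `per_position` (data frame of position, rate, se — or NULL),
#'   `adequacy`, `error_type`, `top_k`, `max_dist`, `read_length`, and for
#'   `error_type = "all"` the per-type `components`.
#' @examples
#' sim <- simulate_reads(genome_length = 20000, n_reads = 50000,
#'                       target_rate = 0.1, seed = 1)
#' fit <- shadow_regression(sim$observed_reads, per_position = FALSE)
#' fit$error_rate
#' @export
shadow_regression <- function(x,
                              error_type = c("substitution", "insertion",
                                             "deletion", "all"),
                              top_k = 1000, max_dist = 2,
                              per_position = TRUE, indel_mask = 2,
                              se_method = c("delta", "bootstrap"),
                              boot_reps = 200, adequacy_warn = TRUE) {
  error_type <- match.arg(error_type)
  se_method <- match.arg(se_method)
  table <- resolve_read_input(x)
  if (length(table$sequences) == 0) stop("no reads left after filtering")
  cl <- match.call()

  if (error_type == "all") {
    comps <- lapply(c("substitution", "insertion", "deletion"), function(et)
      shadow_regression(table, error_type = et, top_k = top_k,
                        max_dist = max_dist, per_position = per_position,
                        indel_mask = indel_mask, se_method = se_method,
                        boot_reps = boot_reps, adequacy_warn = FALSE))
    names(comps) <- c("substitution", "insertion", "deletion")
    pp <- NULL
    if (per_position) {
      pp <- comps[[1]]$per_position
      pp$rate <- rowSums(cbind(comps[[1]]$per_position$rate,
                               comps[[2]]$per_position$rate,
                               comps[[3]]$per_position$rate))
      pp$se <- sqrt(rowSums(cbind(comps[[1]]$per_position$se,
                                  comps[[2]]$per_position$se,
                                  comps[[3]]$per_position$se)^2))
    }
    obj <- structure(list(error_rate = sum(vapply(comps, `[[`, 0, "error_rate")),
                          se = sqrt(sum(vapply(comps, `[[`, 0, "se")^2)),
                          error_type = "all", fit = NULL,
                          points = comps[[1]]$points, per_position = pp,
                          adequacy = comps[[1]]$adequacy, components = comps,
                          top_k = comps[[1]]$top_k, max_dist = max_dist,
                          read_length = table$read_length, call = cl),
                     class = "shadow_regression")
    return(obj)
  }

  adequacy <- coverage_adequacy(table, k = top_k)
  if (adequacy_warn && !adequacy$adequate)
    warning("coverage may be inadequate for shadow regression (max count ",
            adequacy$max_count, ", top-k range ", adequacy$count_range,
            "; both should reach ~500); proceeding anyway")

  targets <- select_top_reads(table, k = top_k)
  prof <- shadow_profiles_matrix(table, targets, exclude = targets,
                                 error_type = error_type, max_dist = max_dist)
  nvec <- table$counts[match(targets, table$sequences)]
  points <- data.frame(read = targets, n = nvec, s = prof$total,
                       stringsAsFactors = FALSE)

  fit <- fit_robust_line(points$n, points$s)
  beta <- fit$slope
  if (beta < 0) {
    warning("negative fitted slope (", signif(beta, 3),
            ") truncated to 0; data look error free")
    beta <- 0
  }
  rate <- beta / (1 + beta)
  se <- switch(se_method,
               delta = error_rate_se(fit),
               bootstrap = bootstrap_rate_se(points, boot_reps))

  pp <- NULL
  if (per_position) {
    L <- table$read_length
    mask <- if (error_type == "substitution") integer() else {
      m <- min(indel_mask, floor(L / 2))
      c(seq_len(m), L - seq_len(m) + 1L)
    }
    rates <- rep(NA_real_, L)
    ses <- rep(NA_real_, L)
    for (i in seq_len(L)) {
      if (i %in% mask) next
      fi <- tryCatch(fit_robust_line(nvec, prof$by_position[, i]),
                     error = function(e) NULL)
      if (is.null(fi)) next
      bi <- max(fi$slope, 0)
      rates[i] <- bi / (1 + bi)
      ses[i] <- error_rate_se(fi)
    }
    pp <- data.frame(position = seq_len(L), rate = rates, se = ses)
  }

  structure(list(error_rate = rate, se = se, error_type = error_type,
                 fit = fit, points = points, per_position = pp,
                 adequacy = adequacy, components = NULL,
                 top_k = length(targets), max_dist = max_dist,
                 read_length = table$read_length, call = cl),
            class = "shadow_regression")
}

resolve_read_input <- function(x) {
  if (inherits(x, "read_count_table")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("input file not found: ", x)
    if (grepl("\\.(fastq|fq)(\\.gz)?$", x, ignore.case = TRUE))
      return(read_fastq(x))
    return(read_count_table(x))
  }
  if (!is.null(names(x))) return(as_read_count_table(x))
  stop("x must be a read_count_table, a named count vector, or a file path")
}

bootstrap_rate_se <- function(points, reps) {
  rates <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(nrow(points), replace = TRUE)
    f <- tryCatch(fit_robust_line(points$n[idx], points$s[idx]),
                  error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    b <- max(f$slope, 0)
    b / (1 + b)
  }, numeric(1))
  sd(rates, na.rm = TRUE)
}

#' @export
print.shadow_regression <- function(x, digits = 4, ...) {
  cat("Shadow regression error-rate estimate\n")
  cat(sprintf("  error type: %s   top-k: %d   max edit distance: %d\n",
              x$error_type, x$top_k, x$max_dist))
  cat(sprintf("  per-read error rate: %s (SE %s)\n",
              format(x$error_rate, digits = digits),
              format(x$se, digits = 3)))
  if (!is.null(x$fit))
    cat(sprintf("  slope %s, intercept %s over %d points\n",
                format(x$fit$slope, digits = digits),
                format(x$fit$intercept, digits = digits), x$fit$n_points))
  if (!x$adequacy$adequate)
    cat("  note: coverage adequacy check FAILED (max count ",
        x$adequacy$max_count, ", range ", x$adequacy$count_range, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.shadow_regression <- function(object, ...) {
  structure(list(object = object), class = "summary.shadow_regression")
}

#' @export
print.summary.shadow_regression <- function(x, ...) {
  o <- x$object
  print(o)
  if (!is.null(o$per_position)) {
    pp <- o$per_position
    ok <- !is.na(pp$rate)
    if (any(ok)) {
      cat("  per-position rates: median ",
          format(median(pp$rate[ok]), digits = 3), ", range [",
          format(min(pp$rate[ok]), digits = 3), ", ",
          format(max(pp$rate[ok]), digits = 3), "]\n", sep = "")
    }
  }
  if (!is.null(o$components)) {
    cat("  components:\n")
    for (nm in names(o$components))
      cat(sprintf("    %-12s %s\n", nm,
                  format(o$components[[nm]]$error_rate, digits = 4)))
  }
  invisible(x)
}

#' @export
coef.shadow_regression <- function(object, ...) {
  if (is.null(object$fit))
    return(setNames(vapply(object$components, `[[`, 0, "error_rate"),
                    names(object$components)))
  c(intercept = object$fit$intercept, slope = object$fit$slope)
}

#' @export
predict.shadow_regression <- function(object, newdata = NULL, ...) {
  if (is.null(object$fit)) stop("no single regression line for error_type='all'")
  n <- if (is.null(newdata)) object$points$n else
    if (is.data.frame(newdata)) newdata$n else as.numeric(newdata)
  object$fit$intercept + object$fit$slope * n
}

#' @export
residuals.shadow_regression <- function(object, ...) {
  if (is.null(object$fit)) stop("no single regression line for error_type='all'")
  object$fit$residuals
}

#' @export
fitted.shadow_regression <- function(object, ...) {
  if (is.null(object$fit)) stop("no single regression line for error_type='all'")
  object$fit$fitted
}

#' Plot a shadow regression
#'
#' `which = "fit"` draws the read-count vs shadow-count scatter with the
#' fitted robust line; `which = "positions"` draws the per-position error-rate
#' profile with +-2 SE bands.
#'
#' @param x a `shadow_regression` object.
#' @param which `"fit"` or `"positions"`.
#' @param ... further arguments passed to [plot()].
#' @export
plot.shadow_regression <- function(x, which = c("fit", "positions"), ...) {
  which <- match.arg(which)
  if (which == "fit") {
    if (is.null(x$fit)) stop("no single regression line for error_type='all'")
    plot(x$points$n, x$points$s, xlab = "read count n_t",
         ylab = "shadow count s_t",
         main = sprintf("Shadow regression (%s)", x$error_type), ...)
    abline(x$fit$intercept, x$fit$slope, col = "red", lwd = 2)
  } else {
    if (is.null(x$per_position)) stop("fitted without per_position = TRUE")
    pp <- x$per_position
    plot(pp$position, pp$rate, type = "b", xlab = "read position",
         ylab = "per-base error rate",
         main = sprintf("Position-specific error rates (%s)", x$error_type), ...)
    ok <- !is.na(pp$rate)
    lines(pp$position[ok], pmax(pp$rate[ok] - 2 * pp$se[ok], 0), lty = 2)
    lines(pp$position[ok], pp$rate[ok] + 2 * pp$se[ok], lty = 2)
  }
  invisible(x)
}
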