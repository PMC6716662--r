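#' Design row for the per-step linear speed model
#'
#' The speed model regresses per-step gait speed on the three per-axis
#' amplitude envelopes and their pairwise interactions:
#' `[1, Ax, Ay, Az, Ax*Ay, Ax*Az, Ay*Az]`.
#'
#' @param steps A `step_events` table (or any data frame with `Ax`, `Ay`,
#'   `Az`).
#' @return Numeric design matrix, one row per step.
#' @export
build_design_row <- function(steps) {
  if (any(!is.finite(steps$Ax)) || any(!is.finite(steps$Ay)) ||
      any(!is.finite(steps$Az)))
    stop("steps with missing amplitudes rejected")
  with(steps, cbind(intercept = 1, Ax = Ax, Ay = Ay, Az = Az,
                    AxAy = Ax * Ay, AxAz = Ax * Az, AyAz = Ay * Az))
}

#' Fit the per-step linear gait-speed model
#'
#' Ordinary least squares of reference speed on the per-step amplitude
#' envelopes Ax, Ay, Az and their pairwise interaction terms. Returns a
#' fitted model object with the usual accessors (`coef`, `print`,
#' `summary`, `predict`).
#'
#' @param steps A `step_events` table with at least 20 rows.
#' @param reference_speeds Positive reference speed per step, m/s.
#' @return An object of class `speed_model`: coefficients, `n_steps`,
#'   `sigma` (residual SD, m/s), and `recipe` (feature-set identifier).
#' @examples
#' set.seed(1)
#' st <- data.frame(Ax = runif(50, 0.5, 2), Ay = runif(50, 0.2, 1),
#'                  Az = runif(50, 0.3, 1.5))
#' v <- 0.1 + 0.4 * st$Ax + rnorm(50, sd = 0.02)
#' m <- fit_speed_model(st, v)
#' coef(m)
#' @export
fit_speed_model <- function(steps, reference_speeds) {
  if (nrow(steps) < 20)
    stop("need at least 20 training steps, got ", nrow(steps))
  if (length(reference_speeds) != nrow(steps))
    stop("one reference speed per step required")
  if (any(reference_speeds <= 0)) stop("reference speeds must be positive")
  X <- build_design_row(steps)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, reference_speeds)
  sigma <- sqrt(sum(fit$residuals^2) / (nrow(X) - ncol(X)))
  structure(list(coefficients = fit$coefficients, n_steps = nrow(X),
                 sigma = sigma, recipe = "amp_pairwise_v1"),
            class = "speed_model")
}

#' @export
print.speed_model <- function(x, ...) {
  cat("<speed_model> per-step gait speed ~ Ax + Ay + Az + pairwise interactions\n")
  cat(sprintf("  fitted on %d steps, residual SD %.4f m/s\n", x$n_steps, x$sigma))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.speed_model <- function(object, ...) {
  cat("Per-step linear gait-speed model (recipe ", object$recipe, ")\n", sep = "")
  print(object)
  invisible(object)
}

#' @export
coef.speed_model <- function(object, ...) object$coefficients

#' Predict per-step gait speed
#'
#' Applies the fitted linear model to each step's amplitude features and
#' clips predictions to the physically plausible range \[0, 3\] m/s.
#'
#' @param object A fitted [fit_speed_model()] object.
#' @param steps A `step_events` table.
#' @param ... Unused.
#' @return Data frame of class `speed_estimates`: `t_start`, `speed` (m/s).
#' @export
predict.speed_model <- function(object, steps, ...) {
  if (is.null(object$coefficients)) stop("model not fitted")
  if (!nrow(steps))
    return(structure(data.frame(t_start = numeric(0), speed = numeric(0)),
                     class = c("speed_estimates", "data.frame")))
  v <- as.numeric(build_design_row(steps) %*% object$coefficients)
  structure(data.frame(t_start = steps$t_start,
                       speed = pmin(pmax(v, 0), 3)),
            class = c("speed_estimates", "data.frame"))
}

#' @rdname predict.speed_model
#' @param model A fitted [fit_speed_model()] object.
#' @export
predict_step_speed <- function(model, steps) predict(model, steps)

#' Mean estimated speed per course section
#'
#' Arithmetic mean of the per-step speed estimates whose `t_start` lies in
#' `[t_start, t_end)` of each section with `include_in_speed = TRUE`.
#' Stairs (and other excluded sections) yield no row; sections without any
#' step yield `NA` with a warning.
#'
#' @param estimates A `speed_estimates` table from [predict.speed_model()].
#' @param sections A [section_definitions()] table.
#' @return Data frame `section`, `speed` (m/s), `n_steps`.
#' @export
aggregate_section_speed <- function(estimates, sections) {
  keep <- sections[sections$include_in_speed, , drop = FALSE]
  out <- lapply(seq_len(nrow(keep)), function(i) {
    sel <- estimates$t_start >= keep$t_start[i] &
      estimates$t_start < keep$t_end[i]
    if (!any(sel)) {
      warning("no steps in section ", keep$name[i])
      return(data.frame(section = keep$name[i], speed = NA_real_,
                        n_steps = 0L, stringsAsFactors = FALSE))
    }
    data.frame(section = keep$name[i], speed = mean(estimates$speed[sel]),
               n_steps = sum(sel), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read a fitted speed model as key=value text
#'
#' One `key=value` line per field; coefficients at full decimal precision,
#' so a written model predicts identically after reading.
#'
#' @param model A `speed_model`.
#' @param path File path.
#' @return `path` (write) or a `speed_model` (read).
#' @export
write_speed_model <- function(model, path) {
  lines <- c(sprintf("recipe=%s", model$recipe),
             sprintf("n_steps=%d", model$n_steps),
             sprintf("sigma=%.17g", model$sigma),
             sprintf("coef_%s=%.17g", names(model$coefficients),
                     model$coefficients))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_speed_model
#' @export
read_speed_model <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  cf <- as.numeric(vals[startsWith(keys, "coef_")])
  names(cf) <- sub("^coef_", "", keys[startsWith(keys, "coef_")])
  structure(list(coefficients = cf,
                 n_steps = as.integer(vals[keys == "n_steps"]),
                 sigma = as.numeric(vals[keys == "sigma"]),
                 recipe = vals[keys == "recipe"]),
            class = "speed_model")
}
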