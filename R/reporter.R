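# Frameshifting-efficiency quantification from dual-reporter assays.
#
# In the dual-reporter construct the upstream beta-galactosidase is always
# translated and the downstream firefly luciferase only when the ribosome
# shifts frame inside the insert.  Efficiency is the ratio of the
# luciferase/beta-gal activity ratio of the test construct to that of the
# in-frame control, in percent; both ratios are construct-level means over
# replicates (test and control replicates are unpaired crude extracts, so a
# ratio of ratio-means, not a mean of replicate-wise ratios of ratios).

.check_reporter <- function(data, label) {
  stopifnot(is.data.frame(data),
            all(c("beta_gal", "luciferase") %in% names(data)))
  if (nrow(data) < 1) abort(paste0(label, " dataset is empty"))
  bad <- which(data$beta_gal <= 0)
  if (length(bad) > 0) {
    abort(paste0("Non-positive beta_gal activity in ", label,
                 " replicate(s) ", paste(bad, collapse = ", "),
                 ": ratio undefined"))
  }
  invisible(data)
}

#' Frameshifting efficiency from test and control reporter measurements
#'
#' `percent = 100 * mean(test luciferase/beta_gal) / mean(control ratio)`;
#' the standard error is propagated to first order from the standard errors
#' of the two ratio means.
#'
#' @param test,ctrl Data frames with columns `beta_gal` and `luciferase`
#'   (one row per replicate).
#' @return One-row tibble: `percent`, `se_percent`, `n_test`, `n_ctrl`.
#' @examples
#' t <- data.frame(beta_gal = c(100, 110), luciferase = c(1.0, 1.1))
#' c0 <- data.frame(beta_gal = c(100, 110), luciferase = c(100, 110))
#' efficiency(t, c0)   # 1 %
#' @export
efficiency <- function(test, ctrl) {
  .check_reporter(test, "test")
  .check_reporter(ctrl, "control")
  rt <- test$luciferase / test$beta_gal
  rc <- ctrl$luciferase / ctrl$beta_gal
  mt <- mean(rt)
  mc <- mean(rc)
  se_t <- stats::sd(rt) / sqrt(length(rt))
  se_c <- stats::sd(rc) / sqrt(length(rc))
  pct <- 100 * mt / mc
  tibble(
    percent = pct,
    se_percent = pct * sqrt((se_t / mt)^2 + (se_c / mc)^2),
    n_test = length(rt), n_ctrl = length(rc)
  )
}

#' Exact Mann-Whitney U test
#'
#' U statistic with mid-rank tie handling and, for `n_x + n_y <= max_exact`,
#' the exact two-sided p value by enumeration of all `choose(n_x+n_y, n_x)`
#' labelings (the probability, under exchangeability, of a U at least as far
#' from its null mean `n_x n_y / 2` as observed).  Larger samples fall back
#' to the tie-corrected normal approximation and are flagged in `method`.
#'
#' @param x,y Numeric vectors.
#' @param max_exact Enumeration limit on `n_x + n_y`.
#' @return One-row tibble: `U`, `p_value`, `method`.
#' @examples
#' mann_whitney_exact(1:3, 4:6)   # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(x, y, max_exact = 20L) {
  nx <- length(x)
  ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_of <- function(idx) sum(rk[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  centre <- nx * ny / 2
  dev_obs <- abs(u_obs - centre)
  if (nx + ny <= max_exact) {
    labelings <- utils::combn(nx + ny, nx)
    devs <- abs(apply(labelings, 2, function(idx) sum(rk[idx])) -
                  nx * (nx + 1) / 2 - centre)
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact"
  } else {
    # normal approximation with tie correction
    n <- nx + ny
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - centre) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  tibble(U = u_obs, p_value = min(p, 1), method = method)
}

#' Read a dual-reporter measurement table
#'
#' @param path TSV with columns `construct`, `replicate`, `beta_gal`,
#'   `luciferase`.
#' @return Tibble of the measurements.
#' @export
read_reporter <- function(path) {
  if (!file.exists(path)) abort(paste0("Reporter file not found: ", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("construct", "replicate", "beta_gal", "luciferase")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0("Reporter table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  as_tibble(d[, need])
}

#' Frameshifting efficiencies for every construct against a control
#'
#' Computes the ratio-of-ratios efficiency and its propagated standard error
#' for each non-control construct, plus the exact Mann-Whitney test of its
#' replicate ratios against the control's (unadjusted, with a Holm-adjusted
#' column for transparency).
#'
#' @param data Long-format measurements (`construct`, `replicate`,
#'   `beta_gal`, `luciferase`).
#' @param control Name of the in-frame control construct.
#' @return Object of class `prf_reporter_fit`; see [tidy.prf_reporter_fit()].
#' @export
reporter_fit <- function(data, control) {
  stopifnot(is.data.frame(data), "construct" %in% names(data))
  if (missing(control) || !control %in% data$construct) {
    abort("`control` must name a construct present in the data")
  }
  ctrl <- data[data$construct == control, ]
  .check_reporter(ctrl, control)
  constructs <- setdiff(unique(data$construct), control)
  res <- purrr::map_dfr(constructs, function(cc) {
    d <- data[data$construct == cc, ]
    .check_reporter(d, cc)
    eff <- efficiency(d, ctrl)
    mw <- mann_whitney_exact(d$luciferase / d$beta_gal,
                             ctrl$luciferase / ctrl$beta_gal)
    mutate(eff, construct = cc, .before = 1) %>%
      mutate(U = mw$U, p_value = mw$p_value, method = mw$method)
  })
  res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
  structure(list(estimates = res, control = control,
                 control_mean_ratio = mean(ctrl$luciferase / ctrl$beta_gal),
                 n_control = nrow(ctrl)),
            class = "prf_reporter_fit")
}

#' @export
print.prf_reporter_fit <- function(x, ...) {
  cat("Dual-reporter frameshifting efficiencies (control: ", x$control,
      ")\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' Tidy per-construct efficiency estimates
#'
#' @param x A `prf_reporter_fit`.
#' @param ... Unused.
#' @return Tibble with one row per test construct: `construct`, `percent`,
#'   `se_percent`, `n_test`, `n_ctrl`, `U`, `p_value`, `method`, `p_holm`.
#' @export
tidy.prf_reporter_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of a reporter fit
#'
#' @param x A `prf_reporter_fit`.
#' @param ... Unused.
#' @return Tibble: `control`, `control_mean_ratio`, `n_control`,
#'   `n_constructs`.
#' @export
glance.prf_reporter_fit <- function(x, ...) {
  tibble(control = x$control, control_mean_ratio = x$control_mean_ratio,
         n_control = x$n_control, n_constructs = nrow(x$estimates))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-construct frameshifting efficiencies
#'
#' @param object A `prf_reporter_fit`.
#' @param ... Unused.
#' @return A ggplot: efficiency (percent, log-friendly) with +-1 SE bars.
#' @export
autoplot.prf_reporter_fit <- function(object, ...) {
  d <- object$estimates
  ggplot2::ggplot(d, ggplot2::aes(x = .data$construct, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$percent - .data$se_percent,
                   ymax = .data$percent + .data$se_percent),
      width = 0.15
    ) +
    ggplot2::labs(x = NULL, y = "Frameshifting efficiency (%)",
                  title = paste0("Relative to in-frame control '",
                                 object$control, "'")) +
    ggplot2::theme_minimal()
}
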