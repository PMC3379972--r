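# broom-style tidiers and ggplot2 autoplot methods for the fitted objects
# and result tables.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a DEC fit
#'
#' @param x A `dec_fit`.
#' @param ... Unused.
#' @return One row per rate: `term`, `estimate`.
#' @export
tidy.dec_fit <- function(x, ...) {
  tibble::tibble(term = c("d", "e"), estimate = c(x$d, x$e))
}

#' @rdname tidy.dec_fit
#' @export
glance.dec_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_tips = x$n_tips,
                 n_states = x$n_states,
                 converged = x$convergence == 0)
}

#' Tidy a GeoSSE ML fit
#'
#' @param x A `geosse_fit`.
#' @param ... Unused.
#' @return One row per rate: `term`, `estimate`, `fixed` (TRUE for `sAB`
#'   under the `no_sab` constraint).
#' @export
tidy.geosse_fit <- function(x, ...) {
  tibble::tibble(term = names(x$pars), estimate = unname(x$pars),
                 fixed = names(x$pars) == "sAB" & x$constraint == "no_sab")
}

#' @rdname tidy.geosse_fit
#' @export
glance.geosse_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_tips = x$n_tips,
                 constraint = x$constraint, n_free = x$n_free,
                 converged = x$convergence == 0)
}

#' Tidy a GeoSSE posterior sample
#'
#' Posterior mean, 95% credible interval and acceptance rate per rate.
#'
#' @param x A `geosse_mcmc`.
#' @param ... Unused.
#' @export
tidy.geosse_mcmc <- function(x, ...) {
  pars <- setdiff(names(x), c("loglik", "logprior"))
  acc <- attr(x, "acceptance")
  dplyr::bind_rows(lapply(pars, function(p) {
    tibble::tibble(term = p, mean = mean(x[[p]]),
                   cred_lo = unname(stats::quantile(x[[p]], 0.025)),
                   cred_hi = unname(stats::quantile(x[[p]], 0.975)),
                   acceptance = unname(acc[p]))
  }))
}

#' @rdname tidy.geosse_mcmc
#' @export
glance.geosse_mcmc <- function(x, ...) {
  tibble::tibble(draws = nrow(x), model = attr(x, "model"),
                 generations = attr(x, "generations"),
                 burnin = attr(x, "burnin"),
                 mean_acceptance = mean(attr(x, "acceptance")))
}

#' Tidy a penalized-likelihood dating fit
#'
#' @param x A `pl_fit`.
#' @param ... Unused.
#' @return One row per internal node: `node`, `age`.
#' @export
tidy.pl_fit <- function(x, ...) {
  nt <- ape::Ntip(x$chronogram)
  nodes <- (nt + 1):(nt + x$chronogram$Nnode)
  tibble::tibble(node = nodes, age = x$ages[nodes])
}

#' @rdname tidy.pl_fit
#' @export
glance.pl_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective,
                 smoothing = x$config$smoothing,
                 crown_age = x$config$calibration_age,
                 rate_cv = stats::sd(x$rates$rate) / mean(x$rates$rate),
                 converged = x$convergence == 0)
}

#' Plot a lineage-through-time curve
#'
#' @param object An `rd_ltt` from [ltt_curve()].
#' @param ... Unused.
#' @return A ggplot (log lineage count vs. age, age axis reversed).
#' @export
autoplot.rd_ltt <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$lineages)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (Ma)", y = "Lineages",
                  title = "Lineages through time")
}

#' Plot events through time
#'
#' @param object An `rd_timeline` from [events_through_time()].
#' @param ... Unused.
#' @export
autoplot.rd_timeline <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("dispersals", "extinctions"),
                              names_to = "kind", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_start, y = .data$count,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = "Events per bin",
                  title = "Biogeographic events through time")
}

#' Plot posterior densities of GeoSSE rates
#'
#' @param object A `geosse_mcmc`.
#' @param ... Unused.
#' @export
autoplot.geosse_mcmc <- function(object, ...) {
  pars <- setdiff(names(object), c("loglik", "logprior"))
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[pars],
                              dplyr::all_of(pars),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "Rate (/Myr)", y = "Posterior density")
}

#' Plot a directed time-slice dispersal matrix
#'
#' @param object An `rd_slices` from [summarize_time_slices()].
#' @param ... Unused.
#' @export
autoplot.rd_slices <- function(object, ...) {
  d <- object$dispersal
  d$slice <- factor(d$slice, levels = c(1, 2),
                    labels = c(paste0("> ", object$boundary, " Ma"),
                               paste0("<= ", object$boundary, " Ma")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::labs(x = "Recipient area", y = "Source area",
                  fill = "Dispersals")
}
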