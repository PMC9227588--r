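#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#' @importFrom stats quantile pchisq qnorm rnorm runif rlnorm sd var
NULL

# internal: stop with a classed condition so tests can target specific failures
stop_fc <- function(message, class) {
  abort(message, class = c(class, "folatecog_error"))
}

# internal: check a single scalar of the given predicate
check_scalar <- function(x, name, predicate, what) {
  if (length(x) != 1L || is.na(x) || !predicate(x)) {
    stop_fc(sprintf("`%s` must be %s.", name, what), "fc_config_error")
  }
  invisible(x)
}

#' Re-exported generics for tidying model objects
#'
#' See [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#'
#' @name tidiers
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
#' @aliases tidy glance augment autoplot
#' @export tidy
#' @export glance
#' @export augment
#' @export autoplot
NULL
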