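# Classed conditions so callers (and the CLI) can dispatch on failure mode.

pk_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "polypka_error"),
                      call = sys.call(-1)))
}

pk_input_error   <- function(msg, ...) pk_stop("polypka_input_error", msg, ...)
pk_parse_error   <- function(msg, ...) pk_stop("polypka_parse_error", msg, ...)
pk_key_error     <- function(msg, ...) pk_stop("polypka_key_error", msg, ...)
pk_missing_state <- function(msg, ...) pk_stop("polypka_missing_state_error", msg, ...)
pk_capacity      <- function(msg, ...) pk_stop("polypka_capacity_error", msg, ...)
pk_integrity     <- function(msg, ...) pk_stop("polypka_data_integrity_error", msg, ...)

# log(sum(exp(x))) without overflow; |G| of real molecules is ~1e5 kcal/mol
# in Hartree-derived scales, so population arithmetic must stay in log space.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
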