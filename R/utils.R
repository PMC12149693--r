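# Internal helpers shared across modules.

# Physical constants (PDG values, MeV-based unit system).
.const <- list(
  K       = 0.307075,     # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
  me      = 0.5109989,    # electron rest energy, MeV
  mp      = 938.2720813,  # proton rest energy, MeV
  N_A     = 6.02214076e23,
  mb_cm2  = 1e-27,        # 1 millibarn in cm^2
  fwhm_sd = 2 * sqrt(2 * log(2))
)

#' Derive a per-stage seed from a global seed
#'
#' Expands one user-facing seed into independent per-stage seeds so that
#' pipeline stages can be re-run in isolation with reproducible streams.
#' Values stay below 2^31 - 1.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = inherit).
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}

# stop() with a class so callers/tests can condition on error types
abort_pg <- function(msg, class) {
  stop(structure(class = c(class, "pg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
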