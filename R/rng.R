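# Self-contained RNG streams. Every stochastic operation in the package
# draws from a stream created here, so results are reproducible from the
# seed and never disturb (or depend on) the caller's global RNG state.

local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  rng_env <- new.env(parent = emptyenv())
  glob <- globalenv()
  saved <- if (exists(".Random.seed", envir = glob, inherits = FALSE)) {
    get(".Random.seed", envir = glob)
  } else NULL
  set.seed(as.integer(seed))
  rng_env$state <- get(".Random.seed", envir = glob)
  if (!is.null(saved)) {
    assign(".Random.seed", saved, envir = glob)
  } else {
    rm(".Random.seed", envir = glob)
  }

  with_state <- function(f) {
    force(f)
    function(...) {
      outer <- if (exists(".Random.seed", envir = glob, inherits = FALSE)) {
        get(".Random.seed", envir = glob)
      } else NULL
      assign(".Random.seed", rng_env$state, envir = glob)
      on.exit({
        rng_env$state <- get(".Random.seed", envir = glob)
        if (!is.null(outer)) {
          assign(".Random.seed", outer, envir = glob)
        } else {
          rm(".Random.seed", envir = glob)
        }
      })
      f(...)
    }
  }

  list(
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    rpois = with_state(stats::rpois),
    rexp = with_state(stats::rexp),
    sample = with_state(function(n, size = n, replace = FALSE, prob = NULL) {
      sample.int(n, size = size, replace = replace, prob = prob)
    }),
    # derive an independent child stream deterministically
    spawn = with_state(function() {
      local_rng(sample.int(.Machine$integer.max, 1))
    })
  )
}
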