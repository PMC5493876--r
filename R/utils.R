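# Seeding helpers: every stochastic stage derives its own sub-stream from the
# user-visible seed plus a stage label, so stages can be re-run independently
# and whole pipelines are reproducible from one integer.

stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))
inv_logit <- function(eta) stats::plogis(eta)
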