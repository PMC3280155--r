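# Local seeding: run `code` under `set.seed(seed)` without disturbing the
# caller's RNG stream (a bare set.seed() inside a package function would
# make two successive "random" calls at the user level identical).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
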