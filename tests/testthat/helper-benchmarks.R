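# Heavy benchmark runs shared by several acceptance tests: computed at
# most once per test session.

.bench_cache <- new.env(parent = emptyenv())

bench_cached <- function(key, expr) {
  if (!exists(key, envir = .bench_cache)) {
    assign(key, expr, envir = .bench_cache)
  }
  get(key, envir = .bench_cache)
}

# Mixed-supervision run on the smoke suite with target snapshots for a
# fixed and two refinable images.
get_smoke_mix_run <- function() {
  bench_cached("smoke_mix", {
    split <- benchmark_suite("smoke", seed = 0)
    split$train <- mark_fixed(split$train, 0.3, seed = 0)
    ids <- vapply(split$train, `[[`, "", "image_id")
    fixed_ids <- ids[vapply(split$train, `[[`, TRUE, "fixed_target")]
    refinable_ids <- setdiff(ids, fixed_ids)
    snapshot_ids <- c(fixed_ids[1], refinable_ids[1:2])
    run <- run_weakly_supervised_training(
      split, initializer_config("circle"),
      desk_schedule(seed = 0, epochs_per_iteration = c(2, 2, 2)),
      loss_mask_params(distance = "euclidean"),
      snapshot_ids = snapshot_ids)
    list(split = split, run = run, snapshot_ids = snapshot_ids,
         fixed_ids = fixed_ids)
  })
}

get_recovery_result <- function() {
  bench_cached("recovery", benchmark_run("recovery", "weak-ci", seed = 0))
}

# 3 seeds x {CI, HI, Mix} on the ordering profile.
get_ordering_results <- function() {
  bench_cached("ordering", {
    variants <- c("weak-ci", "weak-hi", "weak-mix")
    out <- sapply(variants, function(v) {
      vapply(0:2, function(s) {
        benchmark_run("ordering", v, seed = s)$mean_test_dice
      }, 0)
    })
    rownames(out) <- paste0("seed", 0:2)
    out
  })
}
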