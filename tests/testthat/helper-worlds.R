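# Build an astro_world directly from an integer state matrix (bypassing
# create_world) so tests can set up exact configurations.
make_world <- function(states, drug = NULL, step_index = 0L,
                       therapy_start_step = NA_integer_) {
  storage.mode(states) <- "integer"
  w <- list(states = states,
            drug = if (is.null(drug)) matrix(0, nrow(states), ncol(states))
                   else drug,
            step_index = as.integer(step_index),
            therapy_start_step = as.integer(therapy_start_step))
  class(w) <- "astro_world"
  w
}

empty_world <- function(n = 9L, m = n) {
  make_world(matrix(STATE_CODES[["EMPTY"]], n, m))
}

# Single tumor cell at the center of an otherwise empty grid.
lone_tumor_world <- function(n = 9L) {
  w <- empty_world(n)
  ctr <- (n %/% 2L) + 1L
  w$states[ctr, ctr] <- STATE_CODES[["TUMOR"]]
  w
}

# A config whose grid matches a hand-built world; density/pattern fields are
# irrelevant when create_world is bypassed.
world_config <- function(world, ..., interaction = interaction_params(),
                         chemo = NULL) {
  sim_config(rows = nrow(world$states), cols = ncol(world$states),
             density = 0, interaction = interaction, chemo = chemo, ...)
}

# Per-replicate pre-treatment and final tumor counts from a chemo replicate
# table; replicates that never triggered therapy are dropped.
chemo_pre_final <- function(rec) {
  rows <- lapply(split(rec, rec$replicate), function(tr) {
    w <- which(tr$dosing_active)[1]
    if (is.na(w)) return(NULL)
    start <- tr$step[w]
    data.frame(pre = tr$tumor_count[tr$step == start - 1],
               final = tr$tumor_count[tr$step == max(tr$step)])
  })
  do.call(rbind, rows)
}

# Mean final tumor counts over matched-seed replicates; the shared cache
# lets several acceptance checks reuse one set of heavy runs.
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}
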