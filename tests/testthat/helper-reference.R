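# Pure-R reference implementation of one model step, mirroring the compiled
# kernel draw for draw: same agent gathering order (ascending linear index),
# same Fisher-Yates shuffle, same per-agent draw sequence (switch; division,
# placement; death), same drug update. Used to validate the compiled step on
# small grids. Deliberately brute-force: influence sums are double loops.

reference_shuffle <- function(v) {
  n <- length(v)
  if (n < 2) return(v)
  for (i in n:2) {
    j <- min(floor(stats::runif(1) * i), i - 1) + 1
    tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
  }
  v
}

reference_influence <- function(states, i, j, params, kind) {
  nr <- nrow(states); nc <- ncol(states)
  rad <- params$radius
  total <- 0
  for (dr in -rad:rad) for (dc in -rad:rad) {
    if (dr == 0 && dc == 0) next
    r <- i + dr; c <- j + dc
    if (r < 1 || r > nr || c < 1 || c > nc) next
    w <- 1 / (1 + exp(params$kernel_steepness *
                        (sqrt(dr^2 + dc^2) - params$kernel_half_distance)))
    st <- states[r, c]
    if (kind == "tumor") {
      if (st == STATE_CODES[["TUMOR"]]) total <- total + params$kappa * w
    } else {
      if (st == STATE_CODES[["ASTRO_ANTI"]]) total <- total - params$alpha * w
      if (st == STATE_CODES[["ASTRO_PRO"]]) total <- total + params$beta * w
    }
  }
  total
}

reference_step <- function(world, config) {
  ip <- config$interaction
  ch <- config$chemo
  states <- world$states
  drug <- world$drug
  nr <- nrow(states); nc <- ncol(states)
  step_label <- world$step_index + 1L
  dosing <- dosing_active(step_label, world$therapy_start_step,
                          if (is.null(ch)) 14L else ch$steps_on,
                          if (is.null(ch)) 7L else ch$steps_off)

  idx <- seq_len(nr * nc)
  anti <- idx[as.vector(states) == STATE_CODES[["ASTRO_ANTI"]]]
  tumors <- idx[as.vector(states) == STATE_CODES[["TUMOR"]]]

  if (config$switching_enabled) {
    anti <- reference_shuffle(anti)
    for (a in anti) {
      i <- ((a - 1) %% nr) + 1; j <- ((a - 1) %/% nr) + 1
      inorm <- min(reference_influence(states, i, j, ip, "tumor") / ip$i_max, 1)
      p <- 1 / (1 + exp(-ip$switch_sensitivity * (inorm - ip$theta)))
      if (stats::runif(1) < p) states[i, j] <- STATE_CODES[["ASTRO_PRO"]]
    }
  }

  moff <- moore_off_ref()
  tumors <- reference_shuffle(tumors)
  for (t in tumors) {
    i <- ((t - 1) %% nr) + 1; j <- ((t - 1) %/% nr) + 1
    inorm <- reference_influence(states, i, j, ip, "astro") / ip$i_max
    inorm <- max(min(inorm, 1), -1)
    pdiv <- 1 / (1 + exp(-ip$division_sensitivity * inorm))
    if (stats::runif(1) < pdiv) {
      er <- integer(0); ec <- integer(0)
      for (o in seq_len(8)) {
        r <- i + moff[o, 1]; c <- j + moff[o, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            states[r, c] == STATE_CODES[["EMPTY"]]) {
          er <- c(er, r); ec <- c(ec, c)
        }
      }
      if (length(er) > 0) {
        pick <- min(floor(stats::runif(1) * length(er)), length(er) - 1) + 1
        states[er[pick], ec[pick]] <- STATE_CODES[["TUMOR"]]
      }
    }
    if (!is.null(ch) && dosing) {
      npro <- 0
      for (o in seq_len(8)) {
        r <- i + moff[o, 1]; c <- j + moff[o, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            states[r, c] == STATE_CODES[["ASTRO_PRO"]]) npro <- npro + 1
      }
      ceff <- max(drug[i, j] * (1 - ch$G_f * npro / 8), 0)
      pdeath <- 1 / (1 + exp(-ch$k * (ceff - ch$T_half)))
      if (stats::runif(1) < pdeath) states[i, j] <- STATE_CODES[["EMPTY"]]
    }
  }

  if (!is.null(ch)) {
    drug <- diffuse_adi(drug, ch$D_c, dosing, ch$C_b, ch$substeps, ch$rest_bc)
    tmp <- make_world(states)
    drug <- decay_and_uptake(drug, tmp, ch)
  }

  out <- world
  out$states <- states
  out$drug <- drug
  out$step_index <- step_label
  if (!is.null(ch) && is.na(out$therapy_start_step)) {
    if (sum(states == STATE_CODES[["TUMOR"]]) >= ch$start_threshold)
      out$therapy_start_step <- step_label + 1L
  }
  out
}

moore_off_ref <- function() {
  cbind(c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
        c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
}
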