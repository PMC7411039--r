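# Shared fixtures: a small atlas (cheap to build, reused across tests) and
# helpers to construct ground-truth tables and brute-force oracles.

.fixtures <- new.env(parent = emptyenv())

small_atlas <- function() {
  if (is.null(.fixtures$small_atlas))
    .fixtures$small_atlas <- build_atlas(150L, 500L, 2, seed = 3L)
  .fixtures$small_atlas
}

default_atlas <- function() {
  if (is.null(.fixtures$default_atlas))
    .fixtures$default_atlas <- build_atlas(seed = 7L)
  .fixtures$default_atlas
}

# hand-built ground-truth table (one tumor cell per row of `pos` per frame)
make_gt <- function(positions, n_frames, compartment = "INTRAVASCULAR") {
  rows <- do.call(rbind, lapply(seq_len(nrow(positions)), function(i)
    data.frame(cell_id = i, frame = seq_len(n_frames),
               x_px = as.numeric(positions[i, 1]),
               y_px = as.numeric(positions[i, 2]),
               compartment = compartment, kind = "TUMOR")))
  structure(rows, class = c("ground_truth", "data.frame"))
}

# brute-force minimum-cost one-to-one matching (equal-size point sets):
# returns the minimal total squared distance over all permutations
brute_force_match_cost <- function(ax, ay, bx, by) {
  n <- length(ax)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    cost <- sum((ax - bx[p])^2 + (ay - by[p])^2)
    if (cost < best) best <- cost
  }
  best
}

# total squared cost of the links actually made between two frames
linked_cost <- function(ts, f1, f2) {
  a <- ts[ts$frame == f1, ]
  b <- ts[ts$frame == f2, ]
  m <- merge(a, b, by = "track_id")
  sum((m$x_px.x - m$x_px.y)^2 + (m$y_px.x - m$y_px.y)^2)
}
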