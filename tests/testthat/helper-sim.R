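# Shared test utilities: brute-force oracles and small state builders.

# O(N^2) reference neighbour search, written independently of the package's
# vectorised path: plain double loop with explicit minimum-image folding.
brute_force_neighbors <- function(positions, i, radius, L, include_self = FALSE) {
  out <- integer(0)
  for (j in seq_len(nrow(positions))) {
    if (j == i && !include_self) next
    dx <- abs(positions[i, 1] - positions[j, 1])
    dy <- abs(positions[i, 2] - positions[j, 2])
    dx <- min(dx, L - dx)
    dy <- min(dy, L - dy)
    if (sqrt(dx^2 + dy^2) < radius) out <- c(out, j)
  }
  out
}

# Hand-built swarm state with given positions/headings.
make_state <- function(positions, headings, L = 50, v0 = 0.1, t = 0L) {
  structure(list(time_index = t, positions = positions,
                 headings = headings, speed = v0, L = L),
            class = "swarm_state")
}

# Count of adjacent increases in a sequence (0 = monotone non-increasing).
n_inversions <- function(x) sum(diff(x) > 0)
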