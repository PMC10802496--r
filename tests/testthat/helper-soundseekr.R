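# Shared fixture builders (all fixtures are constructed in code).

# Hand-built snout-only pose track visiting chambers in sequence, arena-frame
# cm coordinates. `plan` is a list of segments: list(chamber = id or NA for
# center, frames = n). Chamber segments place the snout at the chamber's port
# radius; center segments at the origin.
make_snout_track <- function(plan, arena = arena_geometry()) {
  rows <- list()
  f <- 1L
  for (seg in plan) {
    n <- seg$frames
    if (is.na(seg$chamber)) {
      x <- rep(0, n); y <- rep(0, n)
    } else {
      th <- 2 * pi * seg$chamber / arena$n_ports
      r <- arena$apothem_out - 3
      x <- rep(r * cos(th), n); y <- rep(r * sin(th), n)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      frame = seq(f, f + n - 1), node = "snout", x = x, y = y
    )
    f <- f + n
  }
  dplyr::bind_rows(rows)
}

# All permutations of a vector (brute-force enumeration oracle; only used
# at tiny sizes).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
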