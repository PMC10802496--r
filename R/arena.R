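#' Octagonal arena geometry
#'
#' Builds the planar geometry of the eight-chamber arena: a regular octagon
#' (side 15 cm, longest diagonal 40 cm) whose periphery is partitioned into
#' eight chambers by transparent dividers running inward from the outer
#' vertices, leaving a 5.5 cm entryway into each chamber. The complement of
#' the chambers inside the octagon is the central region from which all
#' chambers can be reached. Coordinates are in cm with the origin at the arena
#' center; chamber ids run 0-7 counterclockwise from east, each chamber
#' centered on its wall and carrying a nosepoke port at the wall midpoint.
#'
#' The divider tips sit at radius `r` such that the chord between adjacent
#' tips equals the entryway width: `r = w / (2 sin(pi/8))`.
#'
#' @param n_ports Number of ports/chambers (the task uses 8).
#' @param side_length_cm Outer wall length, cm.
#' @param longest_diagonal_cm Vertex-to-vertex diagonal, cm.
#' @param entryway_width_cm Width of each chamber entryway, cm.
#'
#' @return An `arena_geometry` list: `n_ports`, `outer_radius`,
#'   `inner_radius`, `port_positions` (tibble port, x, y),
#'   `chamber_polygons` (list of 4x2 matrices), `divider_segments`
#'   (list of 2x2 matrices), `adjacency` (tibble chamber, left, right),
#'   plus the input dimensions.
#' @examples
#' a <- arena_geometry()
#' a$port_positions
#' @export
arena_geometry <- function(n_ports = 8, side_length_cm = 15,
                           longest_diagonal_cm = 40,
                           entryway_width_cm = 5.5) {
  if (n_ports < 2) abort("`n_ports` must be >= 2")
  k <- n_ports
  R <- longest_diagonal_cm / 2
  half_sector <- pi / k
  r_in <- entryway_width_cm / (2 * sin(half_sector))
  if (r_in >= R) abort("entryway too wide for the arena diagonal")
  centers <- 2 * pi * (0:(k - 1)) / k        # chamber center angles
  vert_lo <- centers - half_sector           # vertex angles bounding chamber
  vert_hi <- centers + half_sector
  apothem_out <- R * cos(half_sector)

  polar <- function(theta, r) cbind(r * cos(theta), r * sin(theta))
  chamber_polygons <- lapply(seq_len(k), function(i) {
    rbind(
      polar(vert_lo[i], r_in),
      polar(vert_lo[i], R),
      polar(vert_hi[i], R),
      polar(vert_hi[i], r_in)
    )
  })
  divider_segments <- lapply(seq_len(k), function(i) {
    rbind(polar(vert_lo[i], r_in), polar(vert_lo[i], R))
  })
  ports <- tibble(
    port = 0:(k - 1),
    x = apothem_out * cos(centers),
    y = apothem_out * sin(centers)
  )
  adjacency <- tibble(
    chamber = 0:(k - 1),
    left = (0:(k - 1) + 1L) %% k,
    right = (0:(k - 1) - 1L) %% k
  )
  structure(
    list(
      n_ports = k,
      side_length_cm = side_length_cm,
      longest_diagonal_cm = longest_diagonal_cm,
      entryway_width_cm = entryway_width_cm,
      outer_radius = R,
      inner_radius = r_in,
      apothem_out = apothem_out,
      chamber_polygons = chamber_polygons,
      divider_segments = divider_segments,
      port_positions = ports,
      adjacency = adjacency
    ),
    class = "arena_geometry"
  )
}

#' @export
print.arena_geometry <- function(x, ...) {
  cat(sprintf(
    "<arena_geometry> %d chambers, side %.1f cm, diagonal %.1f cm, entryway %.1f cm\n",
    x$n_ports, x$side_length_cm, x$longest_diagonal_cm, x$entryway_width_cm
  ))
  invisible(x)
}

# Ray-casting point-in-polygon for a closed polygon given as an n x 2 matrix.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assign positions to arena regions
#'
#' Classifies planar points (cm, arena frame) as inside one of the chambers or
#' in the central region. Points outside the outer octagon are treated as
#' center (tracking jitter can place the snout marginally outside the wall).
#'
#' @param x,y Numeric coordinate vectors, cm.
#' @param arena An [arena_geometry()].
#'
#' @return Integer vector: chamber id 0..n-1, or `NA` for the center region.
#' @export
assign_region <- function(x, y, arena) {
  k <- arena$n_ports
  theta <- atan2(y, x)
  sector <- (round(theta / (2 * pi / k))) %% k
  out <- rep(NA_integer_, length(x))
  for (ch in 0:(k - 1)) {
    idx <- which(sector == ch)
    if (length(idx) == 0) next
    inside <- point_in_polygon(x[idx], y[idx], arena$chamber_polygons[[ch + 1]])
    out[idx[inside]] <- ch
  }
  out
}

#' Are two chambers ring-adjacent?
#'
#' @param a,b Chamber id vectors.
#' @param arena An [arena_geometry()].
#' @return Logical vector.
#' @export
is_adjacent <- function(a, b, arena) {
  k <- arena$n_ports
  d <- (a - b) %% k
  d == 1 | d == (k - 1)
}
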