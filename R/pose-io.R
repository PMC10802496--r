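#' Read and write pose tracks
#'
#' Two interchange dialects are supported. The CSV dialect is a long table
#' with columns `frame`, `node`, `x`, `y` (missing samples as empty/NA). The
#' HDF5 dialect follows SLEAP-style analysis files: a `tracks` dataset of
#' shape frames x nodes x 2 (x, y; missing as NaN) and a `node_names` string
#' dataset. HDF5 support requires the rhdf5 package.
#'
#' @param path File path.
#' @return A long pose tibble (`frame`, `node`, `x`, `y`).
#' @export
read_pose_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "node", "x", "y")
  if (!all(need %in% names(df))) {
    abort("pose CSV needs columns frame, node, x, y")
  }
  as_tibble(df[need])
}

#' @rdname read_pose_csv
#' @param pose Long pose tibble.
#' @export
write_pose_csv <- function(pose, path) {
  utils::write.csv(as.data.frame(pose), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_pose_csv
#' @export
read_pose_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    abort("HDF5 pose input requires the rhdf5 package")
  }
  tracks <- rhdf5::h5read(path, "tracks")
  nodes <- as.character(rhdf5::h5read(path, "node_names"))
  n_frames <- dim(tracks)[1]
  n_nodes <- dim(tracks)[2]
  rows <- lapply(seq_len(n_nodes), function(j) {
    tibble(frame = seq_len(n_frames), node = nodes[j],
           x = as.numeric(tracks[, j, 1]), y = as.numeric(tracks[, j, 2]))
  })
  out <- list_rbind(rows)
  out$x[is.nan(out$x)] <- NA_real_
  out$y[is.nan(out$y)] <- NA_real_
  arrange(out, .data$frame, .data$node)
}

#' @rdname read_pose_csv
#' @export
write_pose_h5 <- function(pose, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    abort("HDF5 pose output requires the rhdf5 package")
  }
  nodes <- unique(pose$node)
  frames <- seq(min(pose$frame), max(pose$frame))
  tracks <- array(NaN, dim = c(length(frames), length(nodes), 2))
  fi <- match(pose$frame, frames)
  ni <- match(pose$node, nodes)
  tracks[cbind(fi, ni, 1L)] <- pose$x
  tracks[cbind(fi, ni, 2L)] <- pose$y
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(tracks, path, "tracks")
  rhdf5::h5write(nodes, path, "node_names")
  rhdf5::h5closeAll()
  invisible(path)
}
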