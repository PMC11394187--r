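# Shared fixtures and independent oracles, built in code at test time.

# Independent connected-component oracle: breadth-first flood fill, written
# against the adjacency definition only (no shared code with the two-pass
# implementation).
flood_fill_labels <- function(vox, adjacency) {
  dims <- dim(vox)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  m <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(adjacency),
                      "6" = m == 1, "18" = m <= 2, "26" = rep(TRUE, 26)), ]
  labels <- array(0L, dims)
  nxt <- 0L
  fg <- which(vox)
  for (start in fg) {
    if (labels[start] > 0) next
    nxt <- nxt + 1L
    queue <- integer(length(fg))
    queue[1] <- start
    labels[start] <- nxt
    head <- 1L; tail <- 1L
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      ci <- arrayInd(cur, dims)
      for (k in seq_len(nrow(offs))) {
        x <- ci[1] + offs$dx[k]; y <- ci[2] + offs$dy[k]; z <- ci[3] + offs$dz[k]
        if (x < 1 || y < 1 || z < 1 || x > dims[1] || y > dims[2] ||
            z > dims[3]) next
        li <- x + dims[1] * ((y - 1) + dims[2] * (z - 1))
        if (vox[li] && labels[li] == 0L) {
          labels[li] <- nxt
          tail <- tail + 1L
          queue[tail] <- li
        }
      }
    }
  }
  labels
}

# Partition equality: same voxel grouping regardless of label numbering.
same_partition <- function(a, b) {
  fa <- a[a > 0 | b > 0]
  fb <- b[a > 0 | b > 0]
  if (any(fa == 0) || any(fb == 0)) return(FALSE)
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(paste(fa, fb))) == length(unique(fb))
}

# Solid cylinder mask along an arbitrary unit axis through the volume centre.
cylinder_mask <- function(dims, spacing, radius_mm, axis = c(0, 0, 1),
                          length_mm = NULL) {
  axis <- axis / sqrt(sum(axis^2))
  centre <- (dims - 1) * spacing / 2
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                   k = 0:(dims[3] - 1))
  p <- cbind(g$i * spacing[1] - centre[1], g$j * spacing[2] - centre[2],
             g$k * spacing[3] - centre[3])
  ax <- p %*% axis
  rad2 <- rowSums(p^2) - ax^2
  keep <- rad2 <= radius_mm^2
  if (!is.null(length_mm)) keep <- keep & abs(ax) <= length_mm / 2
  binary_mask(array(keep, dims), spacing = spacing)
}

# 2D disk patch wrapped as a cross_section (for polar-transform tests).
disk_section <- function(n = 101, pixel_mm = 0.25, radius_px = 10,
                         centre = NULL, extra = NULL, index = 1) {
  if (is.null(centre)) centre <- c((n + 1) / 2, (n + 1) / 2)
  g <- expand.grid(i = 1:n, j = 1:n)
  fg <- (g$i - centre[1])^2 + (g$j - centre[2])^2 <= radius_px^2
  patch <- matrix(as.numeric(fg), n, n)
  if (!is.null(extra)) patch[extra] <- 1
  structure(list(index = index, center = c(0, 0, 0), normal = c(0, 0, 1),
                 u = c(1, 0, 0), v = c(0, 1, 0), patch = patch,
                 pixel_mm = pixel_mm,
                 area_mm2 = sum(patch) * pixel_mm^2, clipped = FALSE),
            class = "cross_section")
}

# Synthetic radius profile for feature/classification tests.
make_profile <- function(section_index, radius, n_bins = 64) {
  r <- rep(radius, length.out = n_bins)
  structure(list(angles = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
                 radius = r, empty = rep(FALSE, n_bins),
                 section_index = section_index),
            class = "radius_profile")
}

# Profile set: baseline radius everywhere except `elevated_idx` sections,
# which get `factor` * baseline over a contiguous angular window.
profile_set <- function(n_sections, elevated_idx, factor = 1.8,
                        baseline = 2.5, n_bins = 64, width_bins = 16) {
  lapply(seq_len(n_sections), function(i) {
    r <- rep(baseline, n_bins)
    if (i %in% elevated_idx) r[1:width_bins] <- baseline * factor
    make_profile(i, r, n_bins)
  })
}
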