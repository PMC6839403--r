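#' Static plot exports
#'
#' Simple base-graphics renderings of the standard analyses: the inhibitor
#' ratio versus radius, the sector count versus radius, a fan plot of the
#' normalized binary strips across annuli, and the colony itself (capsules
#' colored by type; inhibited targets drawn darker).
#'
#' @param prof Result of [radial_profile()] (with strips).
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_radial_ratio <- function(prof, path, width = 800, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  mid <- (prof$r_in_um + prof$r_out_um) / 2
  plot(mid, prof$ratio, type = "b", pch = 16, ylim = c(0, 1),
       xlab = "radius (um)", ylab = "inhibitor ratio I/(I+T)",
       main = "Radial composition")
  graphics::abline(h = 0.5, lty = 2)
  invisible(path)
}

#' @rdname plot_radial_ratio
#' @export
plot_sector_counts <- function(prof, path, width = 800, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  mid <- (prof$r_in_um + prof$r_out_um) / 2
  plot(mid, prof$n_sectors, type = "b", pch = 16,
       xlab = "radius (um)", ylab = "sectors per annulus",
       main = "Sector frequency")
  invisible(path)
}

#' @rdname plot_radial_ratio
#' @export
plot_strip_fan <- function(prof, path, width = 800, height = 800) {
  strips <- attr(prof, "strips")
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  r_max <- max(prof$r_out_um)
  plot(NA, xlim = c(-r_max, r_max), ylim = c(-r_max, r_max), asp = 1,
       xlab = "um", ylab = "um", main = "Normalized sector strips")
  for (a in seq_along(strips)) {
    s <- strips[[a]]
    if (is.null(s)) next
    n <- length(s)
    th0 <- (seq_len(n) - 1) / n * 2 * pi
    th1 <- seq_len(n) / n * 2 * pi
    r0 <- prof$r_in_um[a]; r1 <- prof$r_out_um[a]
    col <- ifelse(s == 1, "#3366cc", "#e69f00")
    for (b in seq_len(n)) {
      th <- seq(th0[b], th1[b], length.out = 6)
      graphics::polygon(c(r0 * cos(th), r1 * cos(rev(th))),
                        c(r0 * sin(th), r1 * sin(rev(th))),
                        col = col[b], border = NA)
    }
  }
  invisible(path)
}

#' @rdname plot_radial_ratio
#' @param snap A `colony_snapshot`.
#' @export
plot_colony <- function(snap, path, width = 1000, height = 1000) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  r_max <- colony_radius(snap) * 1.05 + 1
  plot(NA, xlim = c(-r_max, r_max), ylim = c(-r_max, r_max), asp = 1,
       xlab = "um", ylab = "um",
       main = sprintf("t = %.1f h, %d cells", attr(snap, "time"),
                      nrow(snap)))
  col <- ifelse(snap$cell_type == "inhibitor", "#3366cc",
                ifelse(snap$inhibited == 1, "#cc3333", "#e69f00"))
  x0 <- snap$x_um - snap$length_um / 2 * cos(snap$angle_rad)
  x1 <- snap$x_um + snap$length_um / 2 * cos(snap$angle_rad)
  y0 <- snap$y_um - snap$length_um / 2 * sin(snap$angle_rad)
  y1 <- snap$y_um + snap$length_um / 2 * sin(snap$angle_rad)
  graphics::segments(x0, y0, x1, y1, col = col,
                     lwd = max(1, 300 / r_max), lend = 1)
  invisible(path)
}
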