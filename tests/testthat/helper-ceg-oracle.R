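# Independent consensus-error-grid oracle: explicit zone polygons (built
# from the same published vertex coordinates plus the grid corners) and
# even-odd ray-casting point-in-polygon, checked in risk order. Entirely
# separate from the package's monotone-polyline implementation.

ceg_oracle_polygons <- function() {
  poly <- function(x, y) list(x = x, y = y)
  list(
    A = poly(c(0, 50, 50, 170, 385, 550, 550, 430, 280, 140, 30, 0),
             c(0, 0, 30, 145, 300, 450, 550, 550, 380, 170, 50, 50)),
    B_lower = poly(c(50, 120, 120, 260, 550, 550, 385, 170, 50),
                   c(0, 0, 30, 130, 250, 450, 300, 145, 30)),
    B_upper = poly(c(0, 30, 140, 280, 430, 260, 70, 50, 30, 0),
                   c(50, 50, 170, 380, 550, 550, 110, 80, 60, 60)),
    C_lower = poly(c(120, 250, 250, 550, 550, 260, 120),
                   c(0, 0, 40, 150, 250, 130, 30)),
    C_upper = poly(c(0, 30, 50, 70, 260, 125, 80, 50, 25, 0),
                   c(60, 60, 80, 110, 550, 550, 215, 125, 100, 100)),
    D_lower = poly(c(250, 550, 550, 250), c(0, 0, 150, 40)),
    D_upper = poly(c(0, 25, 50, 80, 125, 50, 35, 0),
                   c(100, 100, 125, 215, 550, 550, 155, 150)),
    E = poly(c(0, 35, 50, 0), c(150, 155, 550, 550)))
}

point_in_polygon <- function(px, py, vx, vy) {
  inside <- rep(FALSE, length(px))
  j <- length(vx)
  for (i in seq_along(vx)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

ceg_zone_oracle <- function(ref, cgm) {
  polys <- ceg_oracle_polygons()
  zone_of <- c(A = "A", B_lower = "B", B_upper = "B", C_lower = "C",
               C_upper = "C", D_lower = "D", D_upper = "D", E = "E")
  out <- rep(NA_character_, length(ref))
  for (nm in names(polys)) {
    hit <- is.na(out) &
      point_in_polygon(ref, cgm, polys[[nm]]$x, polys[[nm]]$y)
    out[hit] <- zone_of[[nm]]
  }
  out
}
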