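# shared small fixtures built in code

tiny_plate <- function() make_flat_plate(4, 0.0125)
tiny_ellipse <- function() make_ellipse(4, 0.125)

# analytic shoelace area of the rounded plate: rectangle (c - t) * t plus a
# full circle of radius t/2
plate_area_exact <- function(c, ratio) {
  t <- ratio * c
  (c - t) * t + pi * (t / 2)^2
}

# brute-force thickness profile of a section along the chord
thickness_scan <- function(p, nbin = 200) {
  m <- do.call(rbind, p$loops)
  br <- seq(min(m[, 1]), max(m[, 1]), length.out = nbin + 1)
  bin <- cut(m[, 1], br, include.lowest = TRUE)
  th <- tapply(m[, 2], bin, function(y) diff(range(y)))
  mid <- (br[-1] + br[-length(br)]) / 2
  data.frame(x = mid, thickness = as.numeric(th))
}
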