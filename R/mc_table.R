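# Marching-cubes triangle table (classic per-cube triangulation) for the 256
# inside/outside corner patterns of a grid cell, corner bit order x + 2y + 4z.
# Vertices lie at cube-edge midpoints, 9 numbers per triangle
# (x1,y1,z1,x2,y2,z2,x3,y3,z3) in unit-cell coordinates; the surface
# estimator re-places each vertex on its edge by linear interpolation.
# Frozen output of a one-off code generator; validated against a
# full-volume marching-cubes run in the tests.
mc_triangle_table <- list(
  NULL,
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 1.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 1.0, 0.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 1.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.0, 0.5, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.0, 0.5, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 1.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 1.0, 0.5, 0.0, 1.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.0, 1.0, 0.5, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 0.0, 0.0, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.0, 0.5, 0.5, 0.0, 0.0, 1.0, 0.5, 0.0, 1.0, 1.0, 0.5, 0.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 1.0, 0.5, 0.5, 1.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 1.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.0, 0.5, 1.0, 0.5, 0.0, 0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 1.0, 0.0, 0.5, 0.5, 1.0, 0.0, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 0.0, 0.0, 0.5, 0.5, 1.0, 0.0, 0.0, 0.0, 0.5, 0.5, 0.0, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 1.0, 0.0, 0.0, 1.0, 0.5, 0.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(0.0, 0.5, 0.0, 0.0, 0.0, 0.5, 1.0, 0.0, 0.5, 0.0, 0.5, 0.0, 1.0, 0.0, 0.5, 1.0, 0.5, 0.0), ncol = 9, byrow = TRUE),
  matrix(c(1.0, 0.5, 0.0, 0.5, 0.0, 0.0, 1.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  matrix(c(0.5, 0.0, 0.0, 0.0, 0.5, 0.0, 0.0, 0.0, 0.5), ncol = 9, byrow = TRUE),
  NULL
)
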