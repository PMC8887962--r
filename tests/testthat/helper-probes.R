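# field-wise probe comparison with absolute tolerance on reals
expect_probe_equal <- function(a, b, tol = 1e-12) {
  expect_identical(probeNdim(a), probeNdim(b))
  expect_identical(siUnits(a), siUnits(b))
  expect_equal(contactPositions(a), contactPositions(b), tolerance = tol)
  expect_identical(contactShapes(a), contactShapes(b))
  expect_equal(contactShapeParams(a), contactShapeParams(b), tolerance = tol)
  expect_equal(contactPlaneAxes(a), contactPlaneAxes(b), tolerance = tol)
  expect_identical(contactIds(a), contactIds(b))
  expect_identical(shankIds(a), shankIds(b))
  expect_identical(deviceChannelIndices(a), deviceChannelIndices(b))
  expect_equal(probeContour(a), probeContour(b), tolerance = tol)
}

# a spread of probes covering the generator space: shapes, staggering,
# multiple shanks, wiring, contours present and absent
make_probe_zoo <- function() {
  tet <- generateTetrode(radius = 12.5, contactRadius = 6)
  squares <- createProbe(2, "mm")
  squares <- setContacts(squares, cbind(c(0, 0.02, 0.04), c(0, 0.02, 0.04)),
                         shapes = "square", shapeParams = list(width = 0.011))
  mixed <- createProbe(2, "um")
  mixed <- setContacts(
    mixed, cbind(0:2 * 15, c(0, 30, 60)),
    shapes = c("circle", "square", "rect"),
    shapeParams = list(list(radius = 5), list(width = 8),
                       list(width = 8, height = 12))
  )
  wired <- setDeviceChannelIndices(
    generateMultiColumnsProbe(numColumns = 2, contactsPerColumn = 4),
    c(7, 5, 3, 1, 6, 4, 2, -1)
  )
  poly3 <- generateMultiColumnsProbe(
    numColumns = 3, contactsPerColumn = c(10, 12, 10),
    xPitch = 18, yPitch = 50, yShiftPerColumn = c(25, 0, 25)
  )
  multishank <- generateMultiShankProbe(
    numShanks = 4, shankPitch = 250, numColumns = 2, contactsPerColumn = 8
  )
  list(tetrode = tet, squares = squares, mixed = mixed, wired = wired,
       poly3 = poly3, multishank = multishank)
}

# brute-force all-pairs distance matrix
pairwise_distances <- function(pos) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    }
  }
  d
}
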