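test_that("JSON write -> read is field-wise identity over the generator space", {
  zoo <- make_probe_zoo()
  # include a 3-d probe and one with contact annotations
  zoo$lifted <- to3d(zoo$multishank)
  zoo$annotated <- local({
    p <- annotateProbe(zoo$tetrode, name = "tet", manufacturer = "lab")
    contactAnnotations(p) <- list(impedance_kohm = c(150, 160, 155, 148))
    p
  })
  for (nm in names(zoo)) {
    f <- withr::local_tempfile(fileext = ".json")
    writeProbeInterface(zoo[[nm]], f)
    g <- readProbeInterface(f)
    expect_identical(numProbes(g), 1L)
    expect_probe_equal(probes(g)[[1]], zoo[[nm]])
  }
  # annotations survive
  f <- withr::local_tempfile(fileext = ".json")
  writeProbeInterface(zoo$annotated, f)
  back <- probes(readProbeInterface(f))[[1]]
  expect_identical(annotations(back)$manufacturer, "lab")
  expect_equal(contactAnnotations(back)$impedance_kohm,
               c(150, 160, 155, 148))
})

test_that("serialization is deterministic: write -> read -> write is byte-identical", {
  p0 <- getFixtureProbe("twoshank32")
  g <- probeGroup(p0, moveProbe(p0, c(600, 0)))
  g <- setGlobalDeviceChannelIndices(g, 0:63)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeProbeInterface(g, f1)
  writeProbeInterface(readProbeInterface(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("multi-probe documents and empty groups round-trip", {
  p0 <- getFixtureProbe("twoshank32")
  g <- probeGroup(p0, moveProbe(p0, c(600, 0)))
  f <- withr::local_tempfile(fileext = ".json")
  writeProbeInterface(g, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_length(doc$probes, 2)
  expect_true(is.character(doc$specifications_version))
  back <- readProbeInterface(f)
  expect_identical(numProbes(back), 2L)
  expect_identical(numContacts(back), 64L)

  writeProbeInterface(probeGroup(list()), f)
  expect_length(jsonlite::fromJSON(f, simplifyVector = FALSE)$probes, 0)
  expect_identical(numProbes(readProbeInterface(f)), 0L)
})

test_that("scalar shape fields broadcast on read", {
  f <- withr::local_tempfile(fileext = ".json")
  pos <- lapply(0:31, function(i) c(0, i * 10))
  jsonlite::write_json(
    list(specifications_version = "0.2", probes = list(list(
      ndim = 2, si_units = "um", annotations = list(name = "bc"),
      contact_positions = pos,
      contact_shapes = "circle",
      contact_shape_params = list(radius = 5)
    ))),
    f, auto_unbox = TRUE, digits = NA
  )
  p <- probes(readProbeInterface(f))[[1]]
  expect_identical(numContacts(p), 32L)
  expect_identical(contactShapes(p), rep("circle", 32))
  expect_identical(contactShapeParams(p), rep(list(list(radius = 5)), 32))
  # optional fields absent -> model defaults
  expect_identical(shankIds(p), rep("0", 32))
  expect_identical(contactIds(p), as.character(0:31))
  expect_length(deviceChannelIndices(p), 0)
})

test_that("the reader rejects each malformed document with a distinct error", {
  write_doc <- function(probe_record) {
    f <- tempfile(fileext = ".json")
    jsonlite::write_json(list(specifications_version = "0.2",
                              probes = list(probe_record)),
                         f, auto_unbox = TRUE, digits = NA)
    f
  }
  base_rec <- list(
    ndim = 2, si_units = "um", annotations = list(),
    contact_positions = list(c(0, 0), c(0, 10)),
    contact_shapes = "circle", contact_shape_params = list(radius = 5)
  )
  # each required field, when missing, is named in the error
  for (field in c("ndim", "si_units", "annotations", "contact_positions",
                  "contact_shapes", "contact_shape_params")) {
    rec <- base_rec
    rec[[field]] <- NULL
    expect_error(readProbeInterface(write_doc(rec)), field, fixed = TRUE)
  }

  rec <- base_rec; rec$contact_shapes <- "hexagon"
  expect_error(readProbeInterface(write_doc(rec)), "hexagon")

  rec <- base_rec
  rec$contact_shapes <- "rect"; rec$contact_shape_params <- list(width = 8)
  expect_error(readProbeInterface(write_doc(rec)), "height")

  rec <- base_rec; rec$contact_shapes <- list("circle", "circle", "circle")
  expect_error(readProbeInterface(write_doc(rec)), "shapes")

  rec <- base_rec; rec$ndim <- 5
  expect_error(readProbeInterface(write_doc(rec)), "ndim")

  rec <- base_rec; rec$contact_positions <- list(c(0, 0, 0), c(0, 10, 0))
  expect_error(readProbeInterface(write_doc(rec)), "coordinates")

  rec <- base_rec; rec$device_channel_indices <- list(3)
  expect_error(readProbeInterface(write_doc(rec)), "device_channel_indices")

  rec <- base_rec; rec$shank_ids <- list("0", "1", "2")
  expect_error(readProbeInterface(write_doc(rec)), "shank")

  # unknown optional keys are tolerated for forward compatibility
  rec <- base_rec; rec$future_field <- "ignored"
  expect_silent(readProbeInterface(write_doc(rec)))

  f <- withr::local_tempfile(fileext = ".json")
  writeLines("not json at all {", f)
  expect_error(readProbeInterface(f))
})

test_that("prb files parse into one probe per channel group", {
  f <- withr::local_tempfile(fileext = ".prb")
  writeLines(c(
    "# toy probe with two channel groups",
    "total_nb_channels = 8",
    "channel_groups = {",
    "    0: {",
    "        'channels': [0, 1, 2, 3],",
    "        'geometry': {0: (0.0, 0.0), 1: (0.0, 50.0),",
    "                     2: (0.0, 100.0), 3: (0.0, 150.0)},",
    "        'graph': [(0, 1), (1, 2)],",
    "    },",
    "    1: {",
    "        'channels': [7, 5, 6, 4],",
    "        'geometry': {4: (200.0, 0.0), 5: (200.0, 50.0),",
    "                     6: (200.0, 100.0), 7: (200.0, 150.0)},",
    "    },",
    "}"
  ), f)
  g <- readPrb(f)
  expect_identical(numProbes(g), 2L)
  expect_identical(vapply(probes(g), numContacts, integer(1)), c(4L, 4L))
  # channels pass through as device indices, in file order
  expect_identical(deviceChannelIndices(probes(g)[[1]]), 0:3)
  expect_identical(deviceChannelIndices(probes(g)[[2]]), c(7L, 5L, 6L, 4L))
  # geometry looked up per channel: row order follows the channels list
  expect_equal(contactPositions(probes(g)[[2]]),
               rbind(c(200, 150), c(200, 50), c(200, 100), c(200, 0)))
  # dialect defaults: circles of radius 5, single shank
  expect_identical(contactShapes(probes(g)[[1]]), rep("circle", 4))
  expect_identical(contactShapeParams(probes(g)[[1]])[[1]], list(radius = 5))

  # independent parse of the same file through Python's literal evaluator
  py <- Sys.which("python")
  if (nzchar(py)) {
    out <- system2(py, c("-c", shQuote(paste0(
      "import ast,json,sys,re\n",
      "src=open(sys.argv[1]).read()\n",
      "m=re.search(r'channel_groups\\s*=',src)\n",
      "d=ast.literal_eval(src[m.end():])\n",
      "print(json.dumps({str(k):{'channels':v['channels'],",
      "'geometry':{str(c):list(xy) for c,xy in v['geometry'].items()}}",
      " for k,v in d.items()}))"
    )), f), stdout = TRUE)
    ref <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
    expect_identical(length(ref), 2L)
    for (k in c("0", "1")) {
      grp <- probes(g)[[match(k, c("0", "1"))]]
      expect_identical(deviceChannelIndices(grp),
                       as.integer(unlist(ref[[k]]$channels)))
      ref_pos <- do.call(rbind, lapply(unlist(ref[[k]]$channels), function(ch) {
        unlist(ref[[k]]$geometry[[as.character(ch)]])
      }))
      expect_equal(contactPositions(grp), ref_pos)
    }
  }

  # degenerate and malformed inputs
  f2 <- withr::local_tempfile(fileext = ".prb")
  writeLines("channel_groups = {}", f2)
  expect_identical(numProbes(readPrb(f2)), 0L)

  writeLines("channel_groups = {0: {'channels': [0, 1]}}", f2)
  expect_error(readPrb(f2), "geometry")

  writeLines("channel_groups = list(range(4))", f2)
  expect_error(readPrb(f2), "not evaluated")

  writeLines("import os", f2)
  expect_error(readPrb(f2))
})

test_that("prb round-trip preserves positions and device indices exactly", {
  p <- generateMultiColumnsProbe(numColumns = 2, contactsPerColumn = 4,
                                 xPitch = 17.5, yPitch = 22.25)
  p <- rotateProbe(p, 13.7)  # irrational coordinates stress full precision
  p <- setDeviceChannelIndices(p, c(5, 3, 1, 7, 0, 2, 4, 6))
  g <- probeGroup(p, setDeviceChannelIndices(moveProbe(p, c(300, 0)),
                                             8:15))
  f <- withr::local_tempfile(fileext = ".prb")
  expect_warning(writePrb(g, f), "dropped")
  back <- readPrb(f)
  expect_identical(numProbes(back), 2L)
  for (k in 1:2) {
    expect_identical(deviceChannelIndices(probes(back)[[k]]),
                     deviceChannelIndices(probes(g)[[k]]))
    expect_identical(contactPositions(probes(back)[[k]]),
                     contactPositions(probes(g)[[k]]))
  }

  # content-stable: model -> prb -> model -> prb gives identical channels
  # and geometry
  f2 <- withr::local_tempfile(fileext = ".prb")
  suppressWarnings(writePrb(back, f2))
  expect_identical(readLines(f), readLines(f2))

  # unwired probes get sequential indices; 3-d probes are rejected
  unwired <- generateTetrode()
  f3 <- withr::local_tempfile(fileext = ".prb")
  suppressWarnings(writePrb(unwired, f3))
  expect_identical(deviceChannelIndices(probes(readPrb(f3))[[1]]), 0:3)
  expect_error(suppressWarnings(writePrb(to3d(unwired), f3)), "2-d")
})
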