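# independent brute-force composition oracle: walk each input through the
# stages one at a time
compose_by_loop <- function(mappings) {
  m <- length(mappings[[1]])
  out <- integer(m)
  for (i in seq_len(m)) {
    cur <- i - 1L
    for (mp in mappings) {
      if (cur < 0L) break
      cur <- mp[cur + 1L]
    }
    out[i] <- cur
  }
  out
}

random_stage_mapping <- function(m, holes = 0L) {
  mp <- sample.int(m) - 1L
  if (holes > 0L) mp[sample.int(m, holes)] <- -1L
  mp
}

test_that("manual wiring assigns device indices in contact order", {
  p <- getFixtureProbe("assy156-standin")
  known <- c(47L, 46L, sample(setdiff(0:63, c(47L, 46L))))
  wired <- setDeviceChannelIndices(p, known)
  expect_identical(deviceChannelIndices(wired)[1:2], c(47L, 46L))

  ident <- setDeviceChannelIndices(p, 0:63)
  expect_identical(deviceChannelIndices(ident), 0:63)

  expect_error(setDeviceChannelIndices(p, 0:10), "per contact")
  expect_error(setDeviceChannelIndices(p, c(0, 0, 1:62)), "distinct")
  expect_error(setDeviceChannelIndices(createProbe(), integer(0)), "contacts")
})

test_that("stage tables validate their mapping", {
  expect_s4_class(stageTable("id", 0:7), "StageTable")
  expect_error(stageTable("dup", c(0, 1, 1, 3)), "distinct")
  expect_error(stageTable("big", c(0, 1, 4, 3)), "< 4")
  expect_error(stageTable("neg", c(0, -2, 1, 3)), ">= -1")
})

test_that("composing stages matches the brute-force loop oracle", {
  expect_identical(
    stageMapping(composeStages(list(stageTable("a", 0:63),
                                    stageTable("b", 0:63)))),
    0:63
  )
  one <- stageTable("only", c(3L, -1L, 0L, 2L))
  expect_identical(stageMapping(composeStages(list(one))), one@mapping)

  set.seed(20)
  for (rep in 1:200) {
    m <- sample(4:64, 1)
    k <- sample(1:3, 1)
    mappings <- lapply(seq_len(k), function(j) {
      random_stage_mapping(m, holes = sample(0:2, 1))
    })
    stages <- lapply(seq_along(mappings), function(j) {
      stageTable(sprintf("s%d", j), mappings[[j]])
    })
    composed <- composeStages(stages)
    # the composite of valid stage tables is itself a valid stage table
    expect_s4_class(composed, "StageTable")
    expect_identical(stageMapping(composed), compose_by_loop(mappings))
  }

  expect_error(
    composeStages(list(stageTable("a", 0:15), stageTable("b", 0:31))),
    "incompatible"
  )
})

test_that("stage composition is associative and inverted by invertStage", {
  set.seed(7)
  for (rep in 1:25) {
    m <- sample(c(8L, 16L, 32L), 1)
    a <- stageTable("a", random_stage_mapping(m, 1L))
    b <- stageTable("b", random_stage_mapping(m))
    c_ <- stageTable("c", random_stage_mapping(m, 1L))
    left <- composeStages(list(composeStages(list(a, b)), c_))
    right <- composeStages(list(a, composeStages(list(b, c_))))
    expect_identical(stageMapping(left), stageMapping(right))

    full <- stageTable("full", random_stage_mapping(m))
    ident <- composeStages(list(full, invertStage(full)))
    expect_identical(stageMapping(ident), seq_len(m) - 1L)
  }
})

test_that("wiring through a registered pathway assigns a permutation", {
  expect_true(all(c("identity64", "reverse64", "synthetic-ASSY-156>RHD2164")
                  %in% listPathways()))

  p <- getFixtureProbe("assy156-standin")
  wired <- wireProbe(p, "synthetic-ASSY-156>RHD2164")
  dci <- deviceChannelIndices(wired)
  expect_length(dci, 64)
  expect_identical(sort(dci), 0:63)

  ident <- wireProbe(p, "identity64")
  expect_identical(deviceChannelIndices(ident), 0:63)
  rev64 <- wireProbe(p, "reverse64")
  expect_identical(deviceChannelIndices(rev64), 63:0)

  # "__" is accepted as a shell-friendly alias for ">"
  wired2 <- wireProbe(p, "synthetic-ASSY-156__RHD2164")
  expect_identical(deviceChannelIndices(wired2), dci)

  small <- getFixtureProbe("twoshank32")
  expect_error(wireProbe(small, "identity64"), "32")
  expect_error(wireProbe(p, "no-such-pathway"), "identity64")
})

test_that("pathway files round-trip through the JSON stage format", {
  pw <- pathway("lab>headstage", list(stageTable("lab", c(2L, 0L, 1L, -1L)),
                                      stageTable("headstage", c(1L, 3L, 0L, 2L))))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "lab__headstage.json")
  jsonlite::write_json(
    list(name = "lab>headstage",
         stages = list(
           list(name = "lab", mapping = c(2L, 0L, 1L, -1L)),
           list(name = "headstage", mapping = c(1L, 3L, 0L, 2L))
         )),
    path, auto_unbox = TRUE
  )
  loaded <- readPathwayFile(path)
  expect_identical(loaded@name, pw@name)
  expect_identical(stageMapping(composeStages(loaded)),
                   stageMapping(composeStages(pw)))

  # a directory added via options() joins the registry
  withr::local_options(neuroprobe.pathwayDirs = dir)
  expect_true("lab>headstage" %in% listPathways())
  got <- getPathway("lab>headstage")
  expect_identical(stageMapping(composeStages(got)), c(0L, 1L, 3L, -1L))
})

test_that("group-level wiring splits indices across probes in order", {
  g <- probeGroup(getFixtureProbe("twoshank32"),
                  moveProbe(getFixtureProbe("twoshank32"), c(600, 0)))
  set.seed(11)
  perm <- sample(0:63)
  wired <- setGlobalDeviceChannelIndices(g, perm)
  # split-then-assign: probe 0 takes entries 1..32, probe 1 entries 33..64
  expect_identical(deviceChannelIndices(probes(wired)[[1]]), perm[1:32])
  expect_identical(deviceChannelIndices(probes(wired)[[2]]), perm[33:64])

  ident <- setGlobalDeviceChannelIndices(g, 0:63)
  expect_identical(deviceChannelIndices(probes(ident)[[2]])[1], 32L)

  expect_error(setGlobalDeviceChannelIndices(g, 0:10), "across the group")
  dup <- 0:63
  dup[1] <- 5L  # 5 now appears twice
  expect_error(setGlobalDeviceChannelIndices(g, dup), "distinct")
})
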