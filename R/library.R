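#' @include io-json.R
NULL

.DEFAULT_LIBRARY_BASE <-
  "https://gin.g-node.org/spikeinterface/probeinterface_library/raw/master"

#' Base URL of the online probe library
#'
#' Resolution order: the `baseUrl` argument of [getProbe()], the
#' `neuroprobe.libraryBase` option, the `NEUROPROBE_LIBRARY_BASE` environment
#' variable, then the public library. A local directory path may be used as
#' base, which is handy for mirrors and tests.
#'
#' @return the configured base URL or directory.
#' @export
probeLibraryBase <- function() {
  opt <- getOption("neuroprobe.libraryBase", NULL)
  if (!is.null(opt)) return(opt)
  env <- Sys.getenv("NEUROPROBE_LIBRARY_BASE", "")
  if (nzchar(env)) return(env)
  .DEFAULT_LIBRARY_BASE
}

#' Local cache directory for downloaded probes
#'
#' Defaults to the per-user cache directory ([tools::R_user_dir()]);
#' override with the `neuroprobe.cacheDir` option or the
#' `NEUROPROBE_CACHE_DIR` environment variable.
#'
#' @return path of the cache directory (not necessarily existing yet).
#' @export
probeCacheDir <- function() {
  opt <- getOption("neuroprobe.cacheDir", NULL)
  if (!is.null(opt)) return(opt)
  env <- Sys.getenv("NEUROPROBE_CACHE_DIR", "")
  if (nzchar(env)) return(env)
  tools::R_user_dir("neuroprobe", "cache")
}

.probeCachePath <- function(manufacturer, probeName, cacheDir) {
  file.path(cacheDir, manufacturer, paste0(probeName, ".json"))
}

.fetchLibraryFile <- function(url, dest) {
  dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
  if (grepl("^(https?|ftp|file)://", url)) {
    status <- tryCatch(
      utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
      error = function(e) -1L, warning = function(w) -1L
    )
    ok <- identical(status, 0L) && file.exists(dest) && file.size(dest) > 0
    if (!ok && file.exists(dest)) unlink(dest)
    ok
  } else {
    # base is a local directory (mirror)
    file.exists(url) && file.copy(url, dest, overwrite = TRUE)
  }
}

#' Retrieve a probe from the online probe library
#'
#' Downloads the JSON description of a vendor probe from the public probe
#' library at `<base>/<manufacturer>/<probe_name>/<probe_name>.json`, parses
#' it with [readProbeInterface()], and returns the probe with `manufacturer`
#' and `probe_name` recorded in its annotations. The downloaded file is
#' cached under [probeCacheDir()], so later calls (including fully offline
#' sessions) are served from the cache without touching the network.
#'
#' @param manufacturer vendor directory in the library (e.g.
#'   `"cambridgeneurotech"`).
#' @param probeName probe model name (e.g. `"ASSY-156-P-1"`).
#' @param baseUrl library base URL or local mirror directory; defaults to
#'   [probeLibraryBase()].
#' @param cacheDir cache directory; defaults to [probeCacheDir()].
#' @param forceDownload re-download even if a cached copy exists.
#' @return a [Probe].
#' @seealso [getFixtureProbe()] for offline synthetic stand-ins.
#' @export
getProbe <- function(manufacturer, probeName,
                     baseUrl = probeLibraryBase(),
                     cacheDir = probeCacheDir(),
                     forceDownload = FALSE) {
  if (!nzchar(manufacturer) || !nzchar(probeName)) {
    .stopValidation("manufacturer and probeName must be non-empty")
  }
  cachePath <- .probeCachePath(manufacturer, probeName, cacheDir)
  url <- paste(baseUrl, manufacturer, probeName,
               paste0(probeName, ".json"), sep = "/")
  if (forceDownload || !file.exists(cachePath)) {
    ok <- .fetchLibraryFile(url, cachePath)
    if (!ok) {
      if (file.exists(cachePath)) {
        # keep serving the stale cache if a forced refresh failed
      } else {
        .stopValidation(paste0(
          "could not retrieve probe '%s/%s' from %s and no cached copy ",
          "exists; check the probe name, or work offline with ",
          "getFixtureProbe()"), manufacturer, probeName, url)
      }
    }
  }
  group <- readProbeInterface(cachePath)
  if (numProbes(group) < 1L) {
    .stopValidation("library file for '%s/%s' contains no probe",
                    manufacturer, probeName)
  }
  probe <- probes(group)[[1]]
  probe@annotations$manufacturer <- probe@annotations$manufacturer %||% manufacturer
  probe@annotations$probe_name <- probe@annotations$probe_name %||% probeName
  probe
}

## ---- offline fixtures -----------------------------------------------------

# Synthetic stand-ins for vendor probes: the contact counts, shank structure
# and column structure follow the vendors' published channel counts, but the
# coordinates are plausible inventions, not vendor geometry files.
.FIXTURE_BUILDERS <- list(
  # 64 contacts on 4 shanks of 16 (2 columns x 8), like a Cambridge
  # Neurotech ASSY-156-P-1 in channel count and shank structure
  "assy156-standin" = function() {
    p <- generateMultiShankProbe(
      numShanks = 4, shankPitch = 250,
      numColumns = 2, contactsPerColumn = 8,
      xPitch = 22.5, yPitch = 25,
      contactShape = "circle", contactShapeParams = list(radius = 10)
    )
    annotateProbe(p, name = "assy156-standin",
                  description = "synthetic stand-in: 64 contacts, 4 shanks x 16")
  },
  # 32 contacts in staggered columns of 10/12/10, like a NeuroNexus
  # A1x32-Poly3-10mm-50-177 in channel count and column structure
  "nn-poly3-standin" = function() {
    p <- generateMultiColumnsProbe(
      numColumns = 3, contactsPerColumn = c(10, 12, 10),
      xPitch = 18, yPitch = 50, yShiftPerColumn = c(25, 0, 25),
      contactShape = "circle", contactShapeParams = list(radius = 7.5)
    )
    annotateProbe(p, name = "nn-poly3-standin",
                  description = "synthetic stand-in: 32 contacts, columns 10/12/10")
  },
  # the from-scratch two-shank teaching layout: 2 shanks x 2 columns x 8
  "twoshank32" = function() {
    p <- generateMultiShankProbe(
      numShanks = 2, shankPitch = 150,
      numColumns = 2, contactsPerColumn = 8,
      xPitch = 20, yPitch = 20,
      contactShape = "circle", contactShapeParams = list(radius = 5)
    )
    annotateProbe(p, name = "twoshank32",
                  description = "two-shank toy probe: 32 contacts, 2 shanks x 16")
  }
)

#' List bundled synthetic fixture probes
#' @return character vector of fixture names accepted by [getFixtureProbe()].
#' @export
listFixtureProbes <- function() names(.FIXTURE_BUILDERS)

#' Construct a bundled synthetic fixture probe
#'
#' Deterministic, fully offline stand-ins for vendor probes: their contact
#' counts and shank/column structure match the vendors' published channel
#' counts, while the coordinates are synthetic (plausible pitches, not vendor
#' geometry). Calling twice with the same name yields identical probes.
#'
#' @param name one of [listFixtureProbes()].
#' @return a [Probe].
#' @examples
#' p <- getFixtureProbe("assy156-standin")
#' numContacts(p)          # 64
#' length(getShanks(p))    # 4
#' @export
getFixtureProbe <- function(name) {
  builder <- .FIXTURE_BUILDERS[[name]]
  if (is.null(builder)) {
    .stopValidation("unknown fixture probe '%s' (available: %s)", name,
                    paste(listFixtureProbes(), collapse = ", "))
  }
  builder()
}
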