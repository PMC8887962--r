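#' @include io-json.R
NULL

## ---- restricted Python-literal parser -------------------------------------
## `.prb` files in the wild are Python source assigning literals (dicts,
## lists, tuples, numbers, strings) to names such as `channel_groups`. They
## are parsed here with a small literal evaluator -- never executed -- so a
## malicious file cannot run code.

.prbTokenize <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- list()
  i <- 1L
  pushTok <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\r", "\n")) {
      i <- i + 1L
    } else if (ch == "#") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
    } else if (ch %in% c("'", "\"")) {
      quote <- ch
      i <- i + 1L
      buf <- character(0)
      closed <- FALSE
      while (i <= n) {
        if (chars[i] == "\\" && i < n) {
          esc <- chars[i + 1L]
          buf <- c(buf, switch(esc, n = "\n", t = "\t", esc))
          i <- i + 2L
        } else if (chars[i] == quote) {
          closed <- TRUE
          i <- i + 1L
          break
        } else {
          buf <- c(buf, chars[i])
          i <- i + 1L
        }
      }
      if (!closed) stop("prb parse error: unterminated string", call. = FALSE)
      pushTok("string", paste(buf, collapse = ""))
    } else if (grepl("[0-9]", ch) ||
               (ch %in% c("-", "+", ".") && i < n && grepl("[0-9.]", chars[i + 1L]))) {
      j <- i
      if (chars[j] %in% c("-", "+")) j <- j + 1L
      while (j <= n && grepl("[0-9._eE]", chars[j])) {
        if (chars[j] %in% c("e", "E") && j < n && chars[j + 1L] %in% c("-", "+")) {
          j <- j + 1L
        }
        j <- j + 1L
      }
      lit <- gsub("_", "", paste(chars[i:(j - 1L)], collapse = ""))
      val <- suppressWarnings(as.numeric(lit))
      if (is.na(val)) stop(sprintf("prb parse error: bad number '%s'", lit), call. = FALSE)
      pushTok("number", val)
      i <- j
    } else if (grepl("[A-Za-z_]", ch)) {
      j <- i
      while (j <= n && grepl("[A-Za-z0-9_]", chars[j])) j <- j + 1L
      pushTok("name", paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (ch %in% c("{", "}", "[", "]", "(", ")", ":", ",", "=")) {
      pushTok(ch, ch)
      i <- i + 1L
    } else {
      stop(sprintf("prb parse error: unexpected character '%s'", ch), call. = FALSE)
    }
  }
  tokens
}

.prbParse <- function(text) {
  tokens <- .prbTokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  advance <- function() {
    tok <- peek()
    if (is.null(tok)) stop("prb parse error: unexpected end of file", call. = FALSE)
    pos <<- pos + 1L
    tok
  }
  expectTok <- function(type) {
    tok <- advance()
    if (tok$type != type) {
      stop(sprintf("prb parse error: expected '%s'", type), call. = FALSE)
    }
    tok
  }
  parseValue <- function() {
    tok <- advance()
    switch(tok$type,
      number = tok$value,
      string = tok$value,
      name = switch(tok$value,
        "True" = TRUE, "False" = FALSE, "None" = NULL,
        stop(sprintf("prb parse error: '%s' is not a literal (code is not evaluated)",
                     tok$value), call. = FALSE)
      ),
      "{" = parseDict(),
      "[" = parseSeq("]"),
      "(" = parseSeq(")"),
      stop(sprintf("prb parse error: unexpected token '%s'", tok$type), call. = FALSE)
    )
  }
  parseDict <- function() {
    out <- list()
    keys <- character(0)
    repeat {
      if (identical(peek()$type, "}")) { advance(); break }
      keyTok <- advance()
      key <- switch(keyTok$type,
        number = format(keyTok$value, scientific = FALSE, trim = TRUE),
        string = keyTok$value,
        stop("prb parse error: dict keys must be numbers or strings", call. = FALSE)
      )
      expectTok(":")
      out[[length(out) + 1L]] <- parseValue()
      keys <- c(keys, key)
      nxt <- advance()
      if (nxt$type == "}") break
      if (nxt$type != ",") stop("prb parse error: expected ',' in dict", call. = FALSE)
    }
    names(out) <- keys
    out
  }
  parseSeq <- function(closing) {
    out <- list()
    repeat {
      if (identical(peek()$type, closing)) { advance(); break }
      out[[length(out) + 1L]] <- parseValue()
      nxt <- advance()
      if (nxt$type == closing) break
      if (nxt$type != ",") stop("prb parse error: expected ',' in sequence", call. = FALSE)
    }
    out
  }
  doc <- list()
  while (!is.null(peek())) {
    nameTok <- expectTok("name")
    expectTok("=")
    doc[[nameTok$value]] <- parseValue()
  }
  doc
}

## ---- prb <-> model --------------------------------------------------------

#' Read a legacy `.prb` probe file
#'
#' The `.prb` dialect used by spike sorters (Klusta, Spyking-CIRCUS) carries
#' only channel lists and a 2-d geometry per *channel group*. Each channel
#' group becomes one [Probe] (groups are the dialect's only notion of device
#' separation): the `channels` entries become the device channel indices, and
#' `geometry` provides the position of each channel, taken in `channels`
#' order. The dialect stores no shape information, so contacts default to
#' circles of radius 5 (in `um`), a single shank, and no contour. `graph`
#' entries are ignored. The file is parsed as Python literals and never
#' executed.
#'
#' @param path path to a `.prb` file.
#' @return a [ProbeGroup] with one probe per channel group.
#' @seealso [writePrb()]
#' @export
readPrb <- function(path) {
  doc <- .prbParse(paste(readLines(path, warn = FALSE), collapse = "\n"))
  cg <- doc$channel_groups
  if (is.null(cg)) {
    .stopValidation("'%s' has no channel_groups", path)
  }
  ps <- lapply(seq_along(cg), function(k) {
    grp <- cg[[k]]
    channels <- unlist(grp$channels, use.names = FALSE)
    if (is.null(grp$geometry)) {
      .stopValidation("channel group %s has no geometry", names(cg)[k])
    }
    pos <- do.call(rbind, lapply(channels, function(chan) {
      key <- format(chan, scientific = FALSE, trim = TRUE)
      g <- grp$geometry[[key]]
      if (is.null(g)) {
        .stopValidation("channel %s of group %s has no geometry entry",
                        key, names(cg)[k])
      }
      unlist(g, use.names = FALSE)
    }))
    probe <- createProbe(2, "um")
    probe <- setContacts(probe, pos, "circle", list(radius = 5))
    probe <- setDeviceChannelIndices(probe, channels)
    probe@annotations <- list(prb_group = names(cg)[k])
    probe
  })
  probeGroup(ps)
}

#' Write probes to a legacy `.prb` file
#'
#' Emits the `channel_groups` structure understood by `.prb`-consuming spike
#' sorters, one channel group per probe keyed by the probe's position in the
#' group. Device channel indices become the `channels` list (sequential
#' indices are assigned if the group is not wired) and each channel maps to
#' its 2-d contact position in `geometry`. The dialect cannot represent
#' contact shapes, plane axes, contours or annotations; these are dropped
#' with a warning. Contacts wired to `-1` have no trace to attach to and are
#' dropped as well. 3-d probes cannot be written.
#'
#' @param x a [Probe] or [ProbeGroup] (2-d).
#' @param path destination file path (conventionally `.prb`).
#' @return `path`, invisibly.
#' @seealso [readPrb()]
#' @export
setMethod("writePrb", "ProbeGroup", function(x, path) {
  validObject(x)
  if (any(vapply(x@probes, function(p) p@ndim, integer(1)) != 2L)) {
    .stopValidation("the .prb dialect is 2-d; use to2d() first")
  }
  dropped <- character(0)
  if (any(vapply(x@probes, function(p) numContacts(p) > 0, logical(1)))) {
    dropped <- c(dropped, "contact shapes/sizes")
  }
  if (any(vapply(x@probes, function(p) nrow(p@contour) > 0, logical(1)))) {
    dropped <- c(dropped, "probe contour")
  }
  if (any(vapply(x@probes, function(p) length(p@annotations) > 0, logical(1)))) {
    dropped <- c(dropped, "annotations")
  }
  lines <- c("channel_groups = {")
  offset <- 0L
  for (k in seq_along(x@probes)) {
    p <- x@probes[[k]]
    n <- numContacts(p)
    dci <- p@deviceChannelIndices
    if (!length(dci)) {
      dci <- offset + seq_len(n) - 1L
      offset <- offset + n
    }
    keep <- which(dci >= 0L)
    chans <- dci[keep]
    lines <- c(lines,
      sprintf("    %d: {", k - 1L),
      sprintf("        'channels': [%s],", paste(chans, collapse = ", ")),
      "        'geometry': {"
    )
    geo <- vapply(seq_along(keep), function(j) {
      xy <- p@positions[keep[j], ]
      sprintf("            %d: [%s, %s]", chans[j],
              .fullPrecision(xy[1]), .fullPrecision(xy[2]))
    }, character(1))
    if (length(geo)) {
      geo[-length(geo)] <- paste0(geo[-length(geo)], ",")
    }
    lines <- c(lines, geo, "        }",
               sprintf("    }%s", if (k < length(x@probes)) "," else ""))
  }
  lines <- c(lines, "}")
  if (length(dropped)) {
    warning(sprintf(".prb cannot represent: %s (dropped)",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  writeLines(lines, path)
  invisible(path)
})

#' @rdname writePrb-ProbeGroup-method
#' @export
setMethod("writePrb", "Probe", function(x, path) {
  writePrb(probeGroup(list(x)), path)
})
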