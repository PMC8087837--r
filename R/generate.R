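# Labeled synthetic dataset generation: image mode renders frames and runs
# the real feature extractor; table mode draws features directly from
# truncated normals centred on each latent mid-range (fast unit-test path).

.TANKS <- c("A1", "A2", "A3", "D1", "D2", "D3", "F1", "F2", "F3",
            "G1", "G2", "G3")
.DATES <- format(seq(as.Date("2019-05-23"), as.Date("2019-09-17"),
                     length.out = 13), "%Y-%m-%d")

#' Construct a GenerationConfig
#'
#' @param profiles list of [MorphProfile-class]; default [defaultProfiles()].
#' @param nPerClass particles per class.
#' @param pixelSizeUm micrometres per pixel (default 0.554).
#' @param imageSidePx frame side in pixels.
#' @param seed integer seed; the config plus seed fully determines the
#'   dataset.
#' @param overlapScale within-class variance inflation (0 = baseline).
#' @param mode `"image"` (render + extract) or `"table"` (direct feature
#'   draws).
#' @param threshold segmentation threshold for image mode.
#' @return A [GenerationConfig-class].
#' @export
GenerationConfig <- function(profiles = defaultProfiles(), nPerClass = 150L,
                             pixelSizeUm = 0.554, imageSidePx = 300L,
                             seed = 1L, overlapScale = 0, mode = "image",
                             threshold = 200) {
  new("GenerationConfig", profiles = profiles,
      nPerClass = as.integer(nPerClass), pixelSizeUm = pixelSizeUm,
      imageSidePx = as.integer(imageSidePx), seed = as.integer(seed),
      overlapScale = overlapScale, mode = mode, threshold = threshold)
}

# truncated normal centred mid-range; sd = quarter width, truncation at the
# (overlap-widened) range ends; inverse-CDF sampling keeps it deterministic
.drawTableFeature <- function(rng, overlapScale = 0) {
  mid <- mean(rng)
  half <- diff(rng) / 2 * (1 + overlapScale)
  sd <- max(diff(rng) / 4 * (1 + overlapScale), 1e-9)
  lo <- stats::pnorm(mid - half, mid, sd)
  hi <- stats::pnorm(mid + half, mid, sd)
  stats::qnorm(stats::runif(1, lo, hi), mid, sd)
}

.tableRow <- function(profile, overlapScale) {
  lat <- profile@latent
  miss <- setdiff(cgFeatureNames(), names(lat))
  if (length(miss))
    stop("table mode needs a latent range for every feature; missing: ",
         paste(miss, collapse = ", "), " in class ", profile@classLabel)
  vapply(cgFeatureNames(),
         function(f) .drawTableFeature(lat[[f]], overlapScale), numeric(1))
}

.newDataset <- function(features, labels, meta) {
  rownames(features) <- NULL; rownames(meta) <- NULL
  new("ParticleDataset", features = features, labels = labels, meta = meta)
}

#' Generate a labeled synthetic dataset
#'
#' Emits exactly `nPerClass` particles per profile (label balance), with
#' synthetic mesocosm metadata (12 tanks, 13 sampling dates, assigned
#' round-robin). In image mode every frame is rendered and the feature row is
#' produced by [extractFeatures()]; optionally the frames, a manifest and the
#' feature table are written under `outDir`. Identical config and seed give a
#' bit-identical dataset.
#'
#' @param config a [GenerationConfig-class].
#' @param outDir optional directory: writes `images/<id>.png`,
#'   `manifest.csv` (columns image_path, class, tank, date, seed) and
#'   `features.csv`.
#' @return A [ParticleDataset-class].
#' @examples
#' cfg <- GenerationConfig(nPerClass = 3, mode = "table", seed = 7)
#' generateDataset(cfg)
#' @export
generateDataset <- function(config, outDir = NULL) {
  stopifnot(is(config, "GenerationConfig"))
  set.seed(config@seed)
  profs <- config@profiles
  n <- config@nPerClass
  rows <- vector("list", length(profs) * n)
  labels <- character(length(rows))
  ids <- character(length(rows))
  images <- if (!is.null(outDir) && config@mode == "image")
    vector("list", length(rows)) else NULL
  k <- 0L
  for (p in profs) {
    safe <- gsub("[^A-Za-z0-9]+", "_", p@classLabel)
    for (i in seq_len(n)) {
      k <- k + 1L
      if (config@mode == "image") {
        rp <- renderParticle(p, config@pixelSizeUm, config@imageSidePx,
                             config@overlapScale)
        rows[[k]] <- extractFeatures(rp$image, config@threshold)
        if (!is.null(images)) images[[k]] <- rp$image
      } else {
        rows[[k]] <- .tableRow(p, config@overlapScale)
      }
      labels[k] <- p@classLabel
      ids[k] <- sprintf("%s_%04d", safe, i)
    }
  }
  features <- as.data.frame(do.call(rbind, rows))
  idx <- seq_len(k) - 1L
  meta <- data.frame(id = ids,
                     tank = .TANKS[idx %% length(.TANKS) + 1L],
                     date = .DATES[(idx %/% length(.TANKS)) %% length(.DATES) + 1L],
                     stringsAsFactors = FALSE)
  ds <- .newDataset(features, labels, meta)
  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- if (is.null(images)) rep(NA_character_, k)
             else file.path("images", paste0(ids, ".png"))
    if (!is.null(images))
      for (j in seq_len(k))
        png::writePNG(images[[j]]@pixels / 255,
                      file.path(outDir, paths[j]))
    manifest <- data.frame(image_path = paths, class = labels,
                           tank = meta$tank, date = meta$date,
                           seed = config@seed, mode = config@mode)
    utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
    writeFeatureTable(ds, file.path(outDir, "features.csv"))
  }
  ds
}

#' Generate a synthetic seasonal series with per-sample class weights
#'
#' Table-mode generation following an explicit schedule of per-(tank, date)
#' class counts, so seasonal patterns (e.g. a morphospecies disappearing
#' mid-season and re-appearing) can be written directly into the generated
#' data and recovered by the downstream abundance aggregation.
#'
#' @param profiles named list of [MorphProfile-class].
#' @param schedule data.frame with columns `tank`, `date`, `class`, `n`.
#' @param seed integer seed.
#' @param overlapScale variance inflation passed to the feature draws.
#' @return A [ParticleDataset-class].
#' @export
generateSeason <- function(profiles, schedule, seed = 1L, overlapScale = 0) {
  stopifnot(all(c("tank", "date", "class", "n") %in% names(schedule)))
  bad <- setdiff(schedule$class, names(profiles))
  if (length(bad))
    stop("schedule classes not in profiles: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  rows <- list(); labels <- character(0); meta <- list()
  k <- 0L
  for (r in seq_len(nrow(schedule))) {
    p <- profiles[[schedule$class[r]]]
    safe <- gsub("[^A-Za-z0-9]+", "_", p@classLabel)
    for (i in seq_len(schedule$n[r])) {
      k <- k + 1L
      rows[[k]] <- .tableRow(p, overlapScale)
      labels[k] <- p@classLabel
      meta[[k]] <- data.frame(
        id = sprintf("%s_%s_%s_%04d", schedule$tank[r],
                     gsub("-", "", schedule$date[r]), safe, i),
        tank = schedule$tank[r], date = .canonDate(schedule$date[r]),
        stringsAsFactors = FALSE)
    }
  }
  .newDataset(as.data.frame(do.call(rbind, rows)), labels,
              do.call(rbind, meta))
}

# accepts ISO yyyy-mm-dd or instrument-style dd/mm/yyyy; stores ISO
.canonDate <- function(x) {
  out <- character(length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{2}/\\d{2}/\\d{4}$", x)
  out[iso] <- x[iso]
  out[dmy] <- format(as.Date(x[dmy], "%d/%m/%Y"), "%Y-%m-%d")
  if (any(!iso & !dmy))
    stop("unparseable date(s): ",
         paste(unique(x[!iso & !dmy]), collapse = ", "))
  out
}

#' Read a GenerationConfig from a YAML file
#'
#' Recognised fields: `nPerClass`, `pixelSizeUm`, `imageSidePx`, `seed`,
#' `overlapScale`, `mode`, `threshold`, and `profiles` (either the string
#' `"default"` or a list of profile blocks mirroring [MorphProfile()]
#' arguments, with `latent`/`envelope` as maps from feature name to
#' `[min, max]`).
#'
#' @param path YAML file path.
#' @return A [GenerationConfig-class].
#' @export
readGenerationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  profiles <- if (is.null(y$profiles) || identical(y$profiles, "default"))
    defaultProfiles()
  else lapply(y$profiles, function(b)
    MorphProfile(b$classLabel, b$nCells, b$cellRadiusUm, b$colonySpreadUm,
                 holeFraction = b$holeFraction %||% 0,
                 haloStrength = b$haloStrength %||% 0,
                 latent = lapply(b$latent, as.numeric),
                 envelope = lapply(b$envelope %||% list(), as.numeric)))
  if (is.list(profiles) && is.null(names(profiles)))
    names(profiles) <- vapply(profiles, classLabel, character(1))
  GenerationConfig(profiles = profiles,
                   nPerClass = y$nPerClass %||% 150L,
                   pixelSizeUm = y$pixelSizeUm %||% 0.554,
                   imageSidePx = y$imageSidePx %||% 300L,
                   seed = y$seed %||% 1L,
                   overlapScale = y$overlapScale %||% 0,
                   mode = y$mode %||% "image",
                   threshold = y$threshold %||% 200)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
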