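## Pipeline orchestration: simulate -> infer -> compose -> summarize,
## driven by a single experiment config (YAML-loadable), with file-based
## subcommand functions and in-memory building blocks.

## Deterministic dye grid in the dipole field of view: one cell per dye,
## spacing larger than one ROI so patterns never overlap. Returns pixel
## centers (nm) and the field side (px). Shared by simulation and inference
## so ROI -> dye association is purely geometric.
ddiGridLayout <- function(nDyes, pitch = 160, spacing = 56L, margin = 30L) {
  k <- ceiling(sqrt(nDyes))
  fov <- 2L * margin + (k - 1L) * spacing + 1L
  idx <- seq_len(nDyes) - 1L
  col <- idx %% k
  row <- idx %/% k
  x <- (margin + col * spacing + 0.5) * pitch
  y <- (margin + row * spacing + 0.5) * pitch
  list(x = x, y = y, fov = fov, k = k, spacing = spacing, margin = margin,
       cell = function(cx, cy) {
         cc <- round((cx - margin - 1L) / spacing)
         rr <- round((cy - margin - 1L) / spacing)
         if (cc < 0 || cc >= k || rr < 0 || rr >= k) return(NA_integer_)
         i <- rr * k + cc + 1L
         if (i > nDyes) NA_integer_ else as.integer(i)
       })
}

## Model prediction for a design on a duplex long enough for stretching.
designPrediction <- function(design, duplex = calibratedDuplex(30)) {
  if (design@n == 0L) intercalationOrientation(duplex, design)
  else stretchingOrientation(duplex, design)
}

#' Simulate one design's experiment in memory
#'
#' Draws per-dye ground-truth orientations about the geometric-model
#' prediction, assigns each dye's origami a uniform random in-plane
#' rotation, and renders the dipole movie (all dyes in one field, camera
#' frame) plus one PAINT movie per origami.
#'
#' @param design a [DesignSpec-class].
#' @param cfg experiment config list (see [normalizeExperimentConfig()]).
#' @param seed integer seed for this design.
#' @return list with \code{ddi}, \code{paints} (list), \code{truth}
#'   (per-dye theta/phi in the origami frame, phiOrigami, grid).
#' @export
simulateDesignExperiment <- function(design, cfg, seed) {
  cfg <- normalizeExperimentConfig(cfg)
  set.seed(seed)
  n <- cfg$dyesPerDesign
  pred <- designPrediction(design)
  center <- predictionAxis(pred)
  axes <- rFisherAxes(n, center, 1 / deg2rad(max(cfg$sigmaTruth, 1e-3))^2)
  ang <- anglesFromAxis(axes)
  phiOrigami <- stats::runif(n, 0, 360)
  grid <- ddiGridLayout(n, cfg$opticsObj@pixelPitch)

  dyes <- data.frame(x = grid$x, y = grid$y,
                     theta = ang$theta,
                     phi = wrapAngle360(ang$phi + phiOrigami),
                     centerTheta = ang$theta, centerPhi = NA_real_,
                     sigmaTruth = cfg$sigmaTruth)
  ## switch redraws happen about the condition center in the camera frame
  cAng <- anglesFromAxis(center)
  dyes$centerTheta <- cAng$theta
  dyes$centerPhi <- wrapAngle360(cAng$phi + phiOrigami)

  ddi <- simulateDdiMovie(dyes, optics = cfg$opticsObj,
                          camera = cfg$cameraObj,
                          kinetics = cfg$kineticsObj,
                          frames = cfg$ddiFrames, fov = grid$fov,
                          defocus = cfg$defocus, seed = seed + 1L)

  pitch <- cfg$opticsObj@pixelPitch
  paintFov <- 64L
  pc <- paintFov / 2 * pitch
  fid <- data.frame(x = pc - 3200, y = pc + 2800, photons = 20000)
  paintOptics <- cfg$opticsObj
  paints <- lapply(seq_len(n), function(d) {
    simulatePaintMovie(
      data.frame(x = pc, y = pc, phiOrigami = phiOrigami[d]),
      layout = defaultOrigamiLayout(), kinetics = cfg$kineticsObj,
      optics = paintOptics, camera = cfg$cameraObj,
      frames = cfg$paintFrames, fiducials = fid, fov = paintFov,
      seed = seed + 100L + d)
  })
  list(ddi = ddi, paints = paints,
       truth = list(theta = ang$theta, phi = wrapAngle360(ang$phi),
                    phiOrigami = phiOrigami, grid = grid,
                    prediction = pred))
}

#' Infer dipole fits from a dipole movie
#'
#' Master image from the first frames, matched-filter ROI extraction,
#' per-ROI segmentation, segment summation and library fitting.
#'
#' @param stack dipole movie array (ADU).
#' @param library a [DipoleLibrary-class].
#' @param camera a [CameraModel-class] (baseline subtraction).
#' @param masterFrames frames summed for the master image.
#' @param maxShift integer ROI recentering search radius, px (the template
#'   fit is very sensitive to mis-centering).
#' @return data.frame: roi, cx, cy, segment, start, end, reason, theta,
#'   phi, defocus, score, accepted.
#' @export
inferDdi <- function(stack, library, camera = cameraModel(),
                     masterFrames = 10L, maxShift = 2L) {
  nf <- dim(stack)[3]
  side <- library@side
  half <- (side - 1L) %/% 2L
  master <- apply(stack[, , seq_len(min(masterFrames, nf)), drop = FALSE],
                  c(1, 2), sum) - min(masterFrames, nf) * camera@baseline
  rois <- extractROIs(master, library)
  out <- NULL
  for (r in seq_len(nrow(rois))) {
    ## the detected center is only pixel-accurate, and the template fit is
    ## very sensitive to mis-centering; search integer shifts with the
    ## coarse fit and keep the best-scoring center
    sh <- min(maxShift,
              rois$x[r] - half - 1L, dim(stack)[1] - half - rois$x[r],
              rois$y[r] - half - 1L, dim(stack)[2] - half - rois$y[r])
    sh <- max(sh, 0L)
    st <- roiStack(stack, c(rois$x[r], rois$y[r]), side + 2L * sh)
    cent <- sh + 1L                      # index of the unshifted crop
    segs <- segmentTimeSeries(st[cent:(cent + side - 1L),
                                 cent:(cent + side - 1L), , drop = FALSE])
    for (s in seq_len(nrow(segs))) {
      if (segs$end[s] - segs$start[s] < 2L) next
      idx <- segs$start[s]:(segs$end[s] - 1L)
      S <- apply(st[, , idx, drop = FALSE], c(1, 2), sum)
      best <- NULL
      for (dx in -sh:sh) for (dy in -sh:sh) {
        crop <- S[(cent + dx):(cent + dx + side - 1L),
                  (cent + dy):(cent + dy + side - 1L)]
        crop <- pmax(crop - roiBorderStats(crop)["baseline"], 0)
        cf <- fitDipole(crop, library, refine = FALSE)
        if (is.null(best) || cf$score > best$score)
          best <- list(score = cf$score, dx = dx, dy = dy, crop = crop)
      }
      fit <- fitDipole(best$crop, library)
      out <- rbind(out, data.frame(
        roi = r, cx = rois$x[r] + best$dx, cy = rois$y[r] + best$dy,
        segment = s, start = segs$start[s], end = segs$end[s],
        reason = segs$reason[s], theta = fit$theta, phi = fit$phi,
        defocus = fit$defocus, score = fit$score, accepted = fit$accepted))
    }
  }
  if (is.null(out))
    out <- data.frame(roi = integer(), cx = integer(), cy = integer(),
                      segment = integer(), start = integer(),
                      end = integer(), reason = character(),
                      theta = numeric(), phi = numeric(),
                      defocus = numeric(), score = numeric(),
                      accepted = logical())
  out
}

#' Infer the origami orientation from a PAINT movie
#'
#' Localizes all frames, drift-corrects with the automatically identified
#' fiducials, removes fiducial localizations, quality-filters, clusters
#' docking sites and registers the template pattern.
#'
#' @param stack PAINT movie array (ADU).
#' @param camera a [CameraModel-class].
#' @param layout an [OrigamiLayout-class] template.
#' @param pitch pixel pitch, nm.
#' @return list with \code{registration} (an
#'   [OrigamiRegistration-class] or NULL when registration failed),
#'   \code{table} (drift-corrected localizations), \code{centroids}.
#' @export
inferPaint <- function(stack, camera = cameraModel(),
                       layout = defaultOrigamiLayout(), pitch = 160) {
  nf <- dim(stack)[3]
  loc <- localizeFrames(stack, camera = camera, pitch = pitch)
  ft <- identifyFiducials(loc, nf)
  if (nrow(ft) == 0L) return(list(registration = NULL, table = loc,
                                  centroids = NULL))
  dc <- driftCorrect(loc, ft, nf)
  tab <- dc$table
  ## drop fiducial localizations
  for (f in unique(ft$fiducial)) {
    tr <- ft[ft$fiducial == f, ]
    tab <- tab[sqrt((tab$x_nm - mean(tr$x_nm))^2 +
                    (tab$y_nm - mean(tr$y_nm))^2) > 400, ]
  }
  tab <- filterLocalizations(tab)
  res <- tryCatch({
    cents <- clusterSites(tab)
    list(registration = registerPattern(cents, layout), centroids = cents)
  }, error = function(e) list(registration = NULL, centroids = NULL))
  list(registration = res$registration, table = tab,
       centroids = res$centroids)
}

#' Run inference for one design's simulated experiment (in memory)
#'
#' @param sim output of [simulateDesignExperiment()].
#' @param library a [DipoleLibrary-class].
#' @param cfg experiment config list.
#' @param design a [DesignSpec-class] (for labeling).
#' @return data.frame of per-segment absolute orientations (one row per
#'   accepted dipole segment with a registered origami).
#' @export
inferDesignExperiment <- function(sim, library, cfg, design) {
  cfg <- normalizeExperimentConfig(cfg)
  ddiFits <- inferDdi(sim$ddi$stack, library, cfg$cameraObj)
  grid <- ddiGridLayout(cfg$dyesPerDesign, cfg$opticsObj@pixelPitch)
  rows <- NULL
  regCache <- list()
  for (i in seq_len(nrow(ddiFits))) {
    dye <- grid$cell(ddiFits$cx[i], ddiFits$cy[i])
    if (is.na(dye)) next
    key <- as.character(dye)
    if (is.null(regCache[[key]]))
      regCache[[key]] <- inferPaint(sim$paints[[dye]]$stack, cfg$cameraObj)
    reg <- regCache[[key]]$registration
    if (is.null(reg) || !reg@registered) next
    abs <- toOrigamiFrame(ddiFits$theta[i], ddiFits$phi[i], reg@phiOrigami)
    rows <- rbind(rows, data.frame(
      design = designLabel(design), dye = dye,
      segment = ddiFits$segment[i],
      theta_dipole = ddiFits$theta[i], phi_dipole = ddiFits$phi[i],
      defocus_nm = ddiFits$defocus[i], score = ddiFits$score[i],
      accepted = ddiFits$accepted[i], phi_origami = reg@phiOrigami,
      reg_rms_nm = reg@rms, theta = abs$theta, phi = abs$phi))
  }
  rows
}

designSeed <- function(baseSeed, designIndex) {
  (baseSeed * 131L + designIndex * 7919L) %% 2000000000L
}

#' Simulate all configured designs to disk
#'
#' Writes, per design, the dipole movie, one PAINT movie per dye, the
#' ground-truth tables and a metadata sidecar. Deterministic for a fixed
#' config seed.
#'
#' @param cfg config list or path to a YAML config.
#' @param outDir output directory (created).
#' @return invisibly, the vector of design directories.
#' @export
runSimulate <- function(cfg, outDir) {
  if (is.character(cfg)) cfg <- readExperimentConfig(cfg)
  cfg <- normalizeExperimentConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dirs <- character(0)
  for (j in seq_along(cfg$designObjs)) {
    design <- cfg$designObjs[[j]]
    lab <- designLabel(design)
    dir <- file.path(outDir, gsub("/", "_", lab))
    dir.create(dir, showWarnings = FALSE)
    sim <- simulateDesignExperiment(design, cfg, designSeed(cfg$seed, j))
    writeMovieTiff(sim$ddi$stack, file.path(dir, "ddi.tif"))
    utils::write.csv(sim$ddi$truth$segments,
                     file.path(dir, "truth_segments.csv"), row.names = FALSE)
    truthDyes <- cbind(sim$ddi$truth$dyes,
                       theta_origami = sim$truth$theta,
                       phi_origami_frame = sim$truth$phi,
                       phiOrigami = sim$truth$phiOrigami)
    utils::write.csv(truthDyes, file.path(dir, "truth_dyes.csv"),
                     row.names = FALSE)
    for (d in seq_along(sim$paints)) {
      writeMovieTiff(sim$paints[[d]]$stack,
                     file.path(dir, sprintf("paint_dye%02d.tif", d)))
      utils::write.csv(sim$paints[[d]]$truth$drift,
                       file.path(dir, sprintf("truth_drift%02d.csv", d)),
                       row.names = FALSE)
    }
    writeMetadataJson(list(design = lab, defocus = cfg$defocus,
                           seed = designSeed(cfg$seed, j),
                           dyes = cfg$dyesPerDesign,
                           ddiFrames = cfg$ddiFrames,
                           paintFrames = cfg$paintFrames),
                      file.path(dir, "meta.json"))
    dirs <- c(dirs, dir)
  }
  invisible(dirs)
}

#' Infer absolute orientations from simulated files
#'
#' @param cfg config list or YAML path (must match the simulate call).
#' @param outDir directory written by [runSimulate()].
#' @param library optional prebuilt [DipoleLibrary-class].
#' @return data.frame of per-segment absolute orientations (also written to
#'   \code{orientations.csv}).
#' @export
runInfer <- function(cfg, outDir, library = NULL) {
  if (is.character(cfg)) cfg <- readExperimentConfig(cfg)
  cfg <- normalizeExperimentConfig(cfg)
  if (is.null(library)) library <- makeDipoleLibrary(cfg$opticsObj)
  all <- NULL
  for (j in seq_along(cfg$designObjs)) {
    design <- cfg$designObjs[[j]]
    dir <- file.path(outDir, gsub("/", "_", designLabel(design)))
    ddiPath <- file.path(dir, "ddi.tif")
    if (!file.exists(ddiPath)) stop("missing simulate output: ", ddiPath)
    stack <- tryCatch(readMovieTiff(ddiPath),
                      error = function(e)
                        stop("cannot read TIFF ", ddiPath, ": ",
                             conditionMessage(e)))
    paints <- lapply(seq_len(cfg$dyesPerDesign), function(d) {
      p <- file.path(dir, sprintf("paint_dye%02d.tif", d))
      if (!file.exists(p)) stop("missing simulate output: ", p)
      list(stack = readMovieTiff(p))
    })
    sim <- list(ddi = list(stack = stack), paints = paints)
    rows <- inferDesignExperiment(sim, library, cfg, design)
    all <- rbind(all, rows)
  }
  if (is.null(all))
    all <- data.frame(design = character(), dye = integer(),
                      segment = integer(), theta_dipole = numeric(),
                      phi_dipole = numeric(), defocus_nm = numeric(),
                      score = numeric(), accepted = logical(),
                      phi_origami = numeric(), reg_rms_nm = numeric(),
                      theta = numeric(), phi = numeric())
  utils::write.csv(all, file.path(outDir, "orientations.csv"),
                   row.names = FALSE)
  all
}

#' Summarize inferred orientations per design
#'
#' Produces per-design Kent condition summaries, overlays the geometric
#' model, and (for intercalation series with at least three attachment
#' positions) fits the wrapped polar angle versus b line.
#'
#' @param cfg config list or YAML path.
#' @param outDir directory holding \code{orientations.csv}.
#' @return list with \code{summary} (per-design data.frame),
#'   \code{predictions} (model table), \code{slopeFit} (or NULL), and
#'   \code{medianErrorDeg} when truth tables are present.
#' @export
runReport <- function(cfg, outDir) {
  if (is.character(cfg)) cfg <- readExperimentConfig(cfg)
  cfg <- normalizeExperimentConfig(cfg)
  orPath <- file.path(outDir, "orientations.csv")
  if (!file.exists(orPath)) stop("missing inference output: ", orPath)
  orient <- utils::read.csv(orPath)
  orient <- orient[orient$accepted %in% TRUE, , drop = FALSE]
  preds <- modelPredictionTable(cfg$designObjs)

  summ <- NULL
  for (design in cfg$designObjs) {
    lab <- designLabel(design)
    rows <- orient[orient$design == lab, , drop = FALSE]
    if (nrow(rows) < 3L) next
    axes <- axisFromAngles(rows$theta, rows$phi)
    cs <- conditionSummary(axes, lab)
    summ <- rbind(summ, cs)
  }
  utils::write.csv(summ, file.path(outDir, "summary.csv"),
                   row.names = FALSE)

  ## slope of the wrapped polar angle vs attachment position for the
  ## unstretched (intercalation) designs
  slopeFit <- NULL
  inter <- Filter(function(d) d@n == 0L && d@strandSign > 0, cfg$designObjs)
  bs <- vapply(inter, function(d) d@b, integer(1))
  if (length(unique(bs)) >= 3L && !is.null(summ)) {
    labs <- vapply(inter, designLabel, character(1))
    rows <- summ[match(labs, summ$design), ]
    ok <- !is.na(rows$theta_mean)
    if (sum(ok) >= 3L) {
      wrap <- vapply(which(ok), function(i)
        equatorialAngle(rows$theta_mean[i], rows$phi_mean[i]), numeric(1))
      slopeFit <- circularLinearFit(bs[ok], wrap, period = 180)
    }
  } else if (length(cfg$designObjs) == 1L) {
    warning("single design: no slope fit")
  }

  ## recovery vs truth when the simulate truth tables are present
  medErr <- NA_real_
  errs <- c()
  for (design in cfg$designObjs) {
    lab <- designLabel(design)
    tp <- file.path(outDir, gsub("/", "_", lab), "truth_dyes.csv")
    if (!file.exists(tp)) next
    truth <- utils::read.csv(tp)
    rows <- orient[orient$design == lab, , drop = FALSE]
    if (nrow(rows) == 0L) next
    tAx <- axisFromAngles(truth$theta_origami, truth$phi_origami_frame)
    mAx <- axisFromAngles(rows$theta, rows$phi)
    errs <- c(errs, axisDistance(mAx, tAx[rows$dye, , drop = FALSE]))
  }
  if (length(errs)) medErr <- stats::median(errs)

  ## plots: mean phi and wrapped theta vs attachment position, with the
  ## model line dashed
  if (!is.null(summ) && nrow(summ) >= 1L) {
    grDevices::pdf(file.path(outDir, "report.pdf"), width = 9, height = 4.5)
    on.exit(grDevices::dev.off())
    graphics::par(mfrow = c(1, 2))
    b <- vapply(cfg$designObjs, function(d) d@b, integer(1))
    m <- match(vapply(cfg$designObjs, designLabel, character(1)),
               summ$design)
    graphics::plot(b, summ$phi_mean[m], pch = 15, xlab = "b (bases)",
                   ylab = expression(phi[mean] ~ "(deg)"),
                   ylim = c(0, 360))
    graphics::abline(h = 90, lty = 2)
    wrapMeas <- rep(NA_real_, length(b))
    for (i in seq_along(b)) if (!is.na(m[i]))
      wrapMeas[i] <- equatorialAngle(summ$theta_mean[m[i]],
                                     summ$phi_mean[m[i]])
    graphics::plot(b, wrapMeas, pch = 15, xlab = "b (bases)",
                   ylab = expression(Theta[mean] ~ "(deg)"),
                   ylim = c(0, 360))
    pb <- preds[match(vapply(cfg$designObjs, designLabel, character(1)),
                      preds$design), ]
    graphics::lines(b[order(b)], wrapAngle360(pb$theta_model_deg)[order(b)],
                    lty = 2)
  }

  utils::write.csv(preds, file.path(outDir, "predictions.csv"),
                   row.names = FALSE)
  list(summary = summ, predictions = preds, slopeFit = slopeFit,
       medianErrorDeg = medErr)
}

#' Log a pipeline step
#'
#' Appends a timestamped line with the config file hash and seed to
#' \code{pipeline.log} in the output directory and echoes it to stderr.
#'
#' @param outDir output directory.
#' @param step step name.
#' @param cfgPath config file path (hashed with md5 when it exists).
#' @param seed seed in effect.
#' @export
logStep <- function(outDir, step, cfgPath = NULL, seed = NA) {
  hash <- if (!is.null(cfgPath) && file.exists(cfgPath))
    unname(tools::md5sum(cfgPath)) else "-"
  line <- sprintf("%s step=%s config_md5=%s seed=%s pkg=%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), step, hash,
                  as.character(seed),
                  as.character(utils::packageVersion("DipoleOrigami")))
  message(line)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cat(line, "\n", file = file.path(outDir, "pipeline.log"), append = TRUE)
  invisible(line)
}
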