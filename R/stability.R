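# Multi-run stability harness: run an identical pipeline configuration
# several times with different seeds and report mean +/- standard deviation
# and maximum of the metrics per reconstruction x post-processing cell.
# On CPU every run is bit-reproducible from its seed, so the harness is also
# the package's reproducibility reference.

#' Pipeline profile: everything one run needs
#'
#' A profile bundles the synthetic data specs, network, sampling, training
#' configuration and the grid of reconstruction x post-processing cells to
#' evaluate. The fixture seeds live in the profile, so every run of a
#' configuration sees the same data and run-to-run variability comes from
#' training stochasticity alone (initialisation, shuffling, augmentation,
#' dropout) — the stability question the harness answers.
#'
#' `profile = "desk"` is the scaled-down CPU profile: a two-level 2D network
#' (16/32 filters), 64x64 patches, 8 training patches per slice, 30 epochs,
#' 3 runs, evaluated as per-patch mosaic, 50%-overlap, 50%-overlap with
#' spline blending, and the latter plus median Z-filtering. `profile =
#' "paper"` is the full-scale recipe (four-level 2D U-Net, 256x256 patches,
#' 360 epochs, 10 runs, the complete reconstruction grid) for users with the
#' budget to run it.
#'
#' @param name `"desk"` or `"paper"`.
#' @return A `pipeline_profile` list with fields `network`, `patch_shape`,
#'   `train_fixture`, `test_fixture`, `sampling`, `train`, `cells`, `n_runs`.
#' @export
pipeline_profile <- function(name = c("desk", "paper")) {
  name <- match.arg(name)
  zf <- list(step = "zfilter", window = 3L)
  if (name == "desk") {
    prof <- list(
      name = name,
      network = network_spec(2, c(16L, 32L), dropout = c(0.1, 0.3)),
      patch_shape = c(64L, 64L),
      train_fixture = fixture_spec(
        shape = c(10L, 192L, 192L), n_organelles = 16L, seed = 1101L
      ),
      test_fixture = fixture_spec(
        shape = c(8L, 128L, 128L), n_organelles = 8L, seed = 2202L
      ),
      sampling = sample_config(patches_per_image = 8L),
      # the 30-epoch desk schedule uses a slightly larger constant learning
      # rate than the full-scale recipe; at 0.002 the short schedule stays in
      # the all-background regime
      train = train_config(learning_rate = 0.005, max_epochs = 30L, patience = 30L),
      cells = list(
        list(label = "per_patch", policy = recon_policy("per_patch"), post = NULL),
        list(label = "overlap_50", policy = recon_policy("overlap_50"), post = NULL),
        list(
          label = "overlap_50+blend",
          policy = recon_policy("overlap_50", blending = "spline"), post = NULL
        ),
        list(
          label = "overlap_50+blend+zfilter",
          policy = recon_policy("overlap_50", blending = "spline"),
          post = postproc_chain(list("binarize", zf))
        )
      ),
      n_runs = 3L
    )
  } else {
    tta <- TRUE
    prof <- list(
      name = name,
      network = preset_spec("unet2d"),
      patch_shape = c(256L, 256L),
      train_fixture = fixture_spec(
        shape = c(48L, 768L, 768L), n_organelles = 160L, seed = 1101L
      ),
      test_fixture = fixture_spec(
        shape = c(24L, 512L, 512L), n_organelles = 60L, seed = 2202L
      ),
      sampling = sample_config(patches_per_image = 12L),
      train = train_config(),
      cells = list(
        list(label = "per_patch", policy = recon_policy("per_patch"), post = NULL),
        list(label = "overlap_50+tta", policy = recon_policy("overlap_50", tta = tta), post = NULL),
        list(
          label = "overlap_50+tta+zfilter",
          policy = recon_policy("overlap_50", tta = tta),
          post = postproc_chain(list("binarize", zf))
        ),
        list(
          label = "overlap_50+blend+tta",
          policy = recon_policy("overlap_50", blending = "spline", tta = tta), post = NULL
        ),
        list(
          label = "overlap_50+blend+tta+zfilter",
          policy = recon_policy("overlap_50", blending = "spline", tta = tta),
          post = postproc_chain(list("binarize", zf))
        ),
        list(label = "full_image+tta", policy = recon_policy("full_image", tta = tta), post = NULL),
        list(
          label = "full_image+tta+zfilter",
          policy = recon_policy("full_image", tta = tta),
          post = postproc_chain(list("binarize", zf))
        )
      ),
      n_runs = 10L
    )
  }
  for (i in seq_along(prof$cells)) {
    prof$cells[[i]]$policy$patch_shape <- prof$patch_shape
  }
  structure(prof, class = "pipeline_profile")
}

#' Execute one training + evaluation run of a profile
#'
#' Generates the profile's fixture volumes, splits the training slices into
#' train/validation, samples class-balanced patches, builds and trains the
#' network with the run seed, predicts the test volume under every
#' reconstruction cell of the profile, applies the cell's post-processing
#' and scores foreground/background/overall IoU against the test labels.
#' Per-patch cells are scored as the unweighted mean over patch-level IoU
#' values; reconstructed cells score the assembled volume.
#'
#' @param profile A [pipeline_profile()].
#' @param seed Run seed (controls initialisation, sampling, shuffling,
#'   augmentation and dropout; not the fixture data).
#' @return A `run_result`: list with `seed`, `best_epoch`, `cells` (data
#'   frame: cell, iou_fg, iou_bg, iou_overall).
#' @export
run_pipeline <- function(profile, seed) {
  stopifnot(inherits(profile, "pipeline_profile"))
  seed <- as.integer(seed)
  tr <- make_volume(profile$train_fixture)
  te <- make_volume(profile$test_fixture)
  nz <- dim(tr$image)[1L]
  scfg <- profile$sampling
  scfg$seed <- seed
  split <- split_train_val(nz, scfg)
  sample_slices <- function(zs, cfg_seed_off) {
    out <- list()
    for (z in zs) {
      cfg <- scfg
      cfg$seed <- seed + cfg_seed_off + z
      out <- c(out, random_patches(
        tr$image[z, , ], tr$labels[z, , ], profile$patch_shape, cfg
      ))
    }
    out
  }
  train_patches <- sample_slices(split$train, 0L)
  val_patches <- sample_slices(split$val, 10000L)
  net <- build_network(profile$network, seed = seed)
  tcfg <- profile$train
  tcfg$seed <- seed
  fit <- train_model(net, train_patches, val_patches, tcfg)

  pred_cache <- new.env(parent = emptyenv())
  cached_predict <- function(pol) {
    key <- paste(pol$mode, pol$blending, pol$tta, sep = "|")
    if (!exists(key, envir = pred_cache)) {
      assign(key, predict_volume(fit$model, te$image, pol), envir = pred_cache)
    }
    get(key, envir = pred_cache)
  }
  rows <- lapply(profile$cells, function(cell) {
    pol <- cell$policy
    if (pol$mode == "per_patch") {
      # average patch-level metric over a 0-overlap grid of every test slice
      vals <- c(fg = 0, bg = 0, ov = 0)
      cnt <- 0L
      for (z in seq_len(dim(te$image)[1L])) {
        grid <- systematic_grid(dim(te$image)[2:3], pol$patch_shape, 0, pad = "shift")
        imgs <- extract_patches(te$image[z, , ], grid)
        labs <- extract_patches(te$labels[z, , ], grid)
        for (i in seq_along(imgs)) {
          pr <- .predict_one(fit$model, imgs[[i]], pol$tta)
          m <- if (is.null(cell$post)) {
            binarize(pr)
          } else {
            run_chain(array(pr, c(1L, dim(pr))), array(imgs[[i]], c(1L, dim(pr))), cell$post)$mask
          }
          r <- iou(m, array(labs[[i]], dim(m) %||% length(m)))
          vals <- vals + c(r$foreground, r$background, r$overall)
          cnt <- cnt + 1L
        }
      }
      vals <- vals / cnt
      data.frame(
        cell = cell$label, iou_fg = vals[[1L]], iou_bg = vals[[2L]], iou_overall = vals[[3L]]
      )
    } else {
      pr <- cached_predict(pol)
      m <- if (is.null(cell$post)) {
        binarize(pr)
      } else {
        run_chain(pr, te$image, cell$post)$mask
      }
      r <- iou(m, te$labels)
      data.frame(
        cell = cell$label, iou_fg = r$foreground, iou_bg = r$background,
        iou_overall = r$overall
      )
    }
  })
  structure(
    list(seed = seed, best_epoch = fit$best_epoch, cells = do.call(rbind, rows)),
    class = "run_result"
  )
}

#' Repeat a configuration across seeds
#'
#' Executes `n` independent runs with seeds `base_seed + 0 .. n-1`. A failed
#' run is recorded as an error entry (keeping its slot in the list of `n`),
#' never silently dropped.
#'
#' @param profile A [pipeline_profile()].
#' @param n Number of runs (the stability protocol uses 10; the desk profile
#'   3).
#' @param base_seed First run seed.
#' @return A `run_results` list of [run_pipeline()] outputs (or error
#'   records).
#' @export
repeat_runs <- function(profile, n = profile$n_runs, base_seed = 1L) {
  stopifnot(n >= 1L)
  out <- lapply(seq_len(n) - 1L, function(i) {
    tryCatch(
      run_pipeline(profile, base_seed + i),
      error = function(e) {
        structure(
          list(seed = base_seed + i, error = conditionMessage(e)),
          class = "run_error"
        )
      }
    )
  })
  structure(out, class = "run_results")
}

#' Summarise repeated runs
#'
#' Per reconstruction x post-processing cell: mean, sample standard deviation
#' (n - 1 denominator; `NA` for a single run) and maximum of the foreground
#' IoU over the runs, plus the mean overall IoU.
#'
#' @param results A `run_results` list from [repeat_runs()] (error records
#'   are skipped but counted in `n_failed`).
#' @return A `stability_summary`: data frame with columns `cell`, `n`,
#'   `mean`, `sd`, `max`, `mean_overall`, and attribute `n_failed`.
#' @export
summarize_runs <- function(results) {
  ok <- Filter(function(r) inherits(r, "run_result"), results)
  if (length(ok) == 0L) stop("no successful runs to summarise")
  cells <- ok[[1L]]$cells$cell
  rows <- lapply(cells, function(cl) {
    fg <- vapply(ok, function(r) r$cells$iou_fg[r$cells$cell == cl], 0)
    ov <- vapply(ok, function(r) r$cells$iou_overall[r$cells$cell == cl], 0)
    data.frame(
      cell = cl, n = length(fg), mean = mean(fg),
      sd = if (length(fg) > 1L) sd(fg) else NA_real_,
      max = max(fg), mean_overall = mean(ov)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failed") <- length(results) - length(ok)
  class(out) <- c("stability_summary", "data.frame")
  out
}

#' Format a stability summary as a Markdown table
#'
#' @param summary A [summarize_runs()] result.
#' @return Character vector of Markdown lines (mean +/- sd and maximum per
#'   cell, in the profile's column order).
#' @export
format_stability_md <- function(summary) {
  fmt <- function(m, s) {
    if (is.na(s)) sprintf("%.3f", m) else sprintf("%.3f±%.3f", m, s)
  }
  c(
    paste("|", paste(c("", summary$cell), collapse = " | "), "|"),
    paste("|", paste(rep("---", nrow(summary) + 1L), collapse = " | "), "|"),
    paste("| mean ± sd |", paste(mapply(fmt, summary$mean, summary$sd), collapse = " | "), "|"),
    paste("| maximum |", paste(sprintf("%.3f", summary$max), collapse = " | "), "|")
  )
}

#' Write a stability summary to CSV
#'
#' @param summary A [summarize_runs()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stability_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
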