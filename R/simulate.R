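# 3D box sums via prefix sums (compiled); w = window sizes per axis.
# Returns, for every admissible window start s (1-based), the sum of arr
# over [s, s + w - 1]; dimensions are dim(arr) - w + 1.
box_sum3 <- function(arr, w) {
  .box_sum3(as.numeric(arr), dim(arr), as.integer(w))
}

#' Sample non-overlapping nodule positions inside the lung
#'
#' Positions are voxel centres drawn uniformly from the admissible set: the
#' voxels at which the nodule's full bounding box fits entirely inside the
#' lung mask. Admissibility is computed exactly with a box-sum filter, so
#' the draw is uniform over admissible voxels rather than
#' rejection-sampled. Pairwise 3D bounding boxes of accepted positions may
#' not overlap; overlapping draws are retried up to `max_tries` times per
#' nodule.
#'
#' @param lung a `lung_mask` from [segment_lung()].
#' @param nodule_extents_mm list of per-axis extents (mm), one per nodule;
#'   a single length-3 vector or scalar is also accepted per element.
#' @param seed integer seed.
#' @param max_tries retry budget per nodule for the overlap constraint.
#' @return list of 0-based voxel index triples `(IS, AP, RL)`.
#' @export
sample_positions <- function(lung, nodule_extents_mm, seed = 1,
                             max_tries = 200) {
  stopifnot(inherits(lung, "lung_mask"))
  if (length(nodule_extents_mm) == 0L) return(list())
  if (lung$empty) stop_placement("lung mask is empty")
  d <- dim(lung$voxels)
  mask_num <- array(as.numeric(lung$voxels), d)
  boxes <- lapply(nodule_extents_mm, function(e) {
    e <- rep(as.numeric(e), length.out = 3)
    pmax(ceiling(e / lung$spacing), 1L)
  })
  admissible <- list()   # cached per distinct box size
  get_admissible <- function(w) {
    key <- paste(w, collapse = "x")
    if (is.null(admissible[[key]])) {
      bs <- box_sum3(mask_num, w)
      ok <- which(bs >= prod(w) - 0.5)
      admissible[[key]] <<- list(starts = ok, dim = dim(bs))
    }
    admissible[[key]]
  }
  with_seed(seed, {
    placed <- list()
    for (i in seq_along(boxes)) {
      w <- boxes[[i]]
      adm <- get_admissible(w)
      if (length(adm$starts) == 0L)
        stop_placement(sprintf(
          "nodule %d (box %s voxels) cannot fit inside the lung mask",
          i, paste(w, collapse = "x")))
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- adm$starts[sample.int(length(adm$starts), 1L)]
        start <- arrayInd(s, adm$dim)[1, ]          # 1-based box start
        lo <- start; hi <- start + w - 1L
        overlap <- any(vapply(placed, function(p)
          all(lo <= p$hi & hi >= p$lo), logical(1)))
        if (!overlap) {
          placed[[i]] <- list(lo = lo, hi = hi,
                              center = (lo + hi) / 2 - 1)  # 0-based centre
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop_placement(sprintf(
          "nodule %d: no non-overlapping position found in %d tries",
          i, max_tries))
    }
    lapply(placed, `[[`, "center")
  })
}

#' Parallel-beam forward projection
#'
#' Projects a 3D attenuation grid along one canonical anatomical axis. Each
#' output pixel is the ray sum of attenuation weighted by the voxel size
#' along the ray (mm converted to cm), i.e. a dimensionless optical depth.
#' The default anterior-posterior axis yields the posteroanterior view.
#'
#' @param mu 3D array of linear attenuation, cm^-1, canonical
#'   `(IS, AP, RL)` order.
#' @param spacing per-axis voxel size, mm.
#' @param axis ray direction: `"AP"` (default), `"IS"` or `"RL"`.
#' @return a [radiograph()] of kind `"raw_line_integral"`; for `"AP"` the
#'   image axes are (IS rows, RL columns).
#' @export
forward_project <- function(mu, spacing, axis = c("AP", "IS", "RL")) {
  axis <- match.arg(axis)
  if (!is.array(mu) || length(dim(mu)) != 3L)
    stop_validation("`mu` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop_validation("`spacing` must be three positive mm values")
  ray_dim <- match(axis, c("IS", "AP", "RL"))
  keep <- setdiff(1:3, ray_dim)
  perm <- c(ray_dim, keep)
  px <- colSums(aperm(mu, perm)) * spacing[ray_dim] / 10   # mm -> cm
  radiograph(px, spacing[keep], kind = "raw_line_integral")
}

# pad a matrix to square with zeros, centred; returns matrix + row/col offsets
pad_square <- function(m) {
  n <- max(dim(m))
  out <- matrix(0, n, n)
  r0 <- (n - nrow(m)) %/% 2
  c0 <- (n - ncol(m)) %/% 2
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  list(m = out, r0 = r0, c0 = c0)
}

com_of_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)   # 0-based (col, row)
}

# compose a simulated radiograph from a cached clean projection and a list
# of per-nodule projections already embedded at full size
compose_radiograph <- function(clean_proj, nodule_projs, records, spacing,
                               out_size, case_id = "case", provenance = list()) {
  dis <- clean_proj$pixels
  for (np in nodule_projs) dis <- dis + np
  pad <- pad_square(dis)
  n_in <- nrow(pad$m)
  img_raw <- resize_matrix(pad$m, c(out_size, out_size), "bilinear")
  img_raw[img_raw < 0] <- 0
  px_mm <- n_in * clean_proj$pixel_spacing[1] / out_size  # isotropic source
  gt <- list()
  if (length(nodule_projs)) {
    for (i in seq_along(nodule_projs)) {
      m <- pad_square(nodule_projs[[i]] > 0)$m
      mm <- resize_matrix(m + 0, c(out_size, out_size), "area") > 0.5
      if (!any(mm))
        stop_validation(sprintf("lesion %d ground-truth mask vanished on resize", i))
      gt[[i]] <- mm
      com <- com_of_mask(mm)
      records$com_x[i] <- com[["x"]]
      records$com_y[i] <- com[["y"]]
    }
  }
  raw <- radiograph(img_raw, px_mm, kind = "raw_line_integral")
  structure(list(image = display_radiograph(raw), raw = raw, gt_masks = gt,
                 records = records, case_id = case_id,
                 provenance = provenance),
            class = "simulated_radiograph")
}

#' @export
print.simulated_radiograph <- function(x, ...) {
  cat(sprintf("<simulated_radiograph> '%s': %d x %d px, %d lesion(s)\n",
              x$case_id, nrow(x$image$pixels), ncol(x$image$pixels),
              nrow(x$records)))
  invisible(x)
}

# project a rasterised nodule grid placed at a 0-based centre position into
# a full-size 2D projection (AP axis)
project_nodule_at <- function(grid, center, vol_dim, spacing) {
  gd <- dim(grid)
  start <- round(center - (gd - 1) / 2) + 1L      # 1-based start in volume
  proj_small <- colSums(aperm(grid, c(2, 1, 3))) * spacing[2] / 10
  out <- matrix(0, vol_dim[1], vol_dim[3])
  rows <- start[1] + seq_len(gd[1]) - 1L
  cols <- start[3] + seq_len(gd[3]) - 1L
  rok <- rows >= 1 & rows <= vol_dim[1]
  cok <- cols >= 1 & cols <= vol_dim[3]
  out[rows[rok], cols[cok]] <- proj_small[rok, cok, drop = FALSE]
  out
}

#' Simulation configuration
#'
#' @param attenuation an [attenuation_model()].
#' @param intensity a [nodule_intensity_model()].
#' @param out_size output image size in pixels (square).
#' @param axis projection axis for the view; `"AP"` gives the
#'   posteroanterior radiograph.
#' @export
sim_config <- function(attenuation = attenuation_model(),
                       intensity = nodule_intensity_model(model = attenuation),
                       out_size = 512, axis = "AP") {
  if (out_size < 8) stop_validation("out_size too small")
  structure(list(attenuation = attenuation, intensity = intensity,
                 out_size = as.integer(out_size), axis = axis),
            class = "sim_config")
}

#' Simulate a diseased radiograph with ground truth
#'
#' Forward-projects the (table-removed) clean volume and each placed nodule
#' separately; the diseased image is their sum, and each lesion's perfect
#' ground-truth mask is the support of its own projection. Image and masks
#' are padded to square and resized to `out_size` x `out_size`; lesion
#' centres of mass are recomputed on the resized masks.
#'
#' @param volume a preprocessed [ct_volume()] (table removed).
#' @param nodules list of `list(nodule =, position =)` with positions from
#'   [sample_positions()] (0-based voxel centres).
#' @param config a [sim_config()].
#' @param case_id case label for the records.
#' @return a `simulated_radiograph`: display and raw [radiograph()]s,
#'   per-lesion logical `gt_masks`, a `records` tibble (case_id, lesion_id,
#'   com_x, com_y, diameter_mm, shape_id), and provenance.
#' @export
make_radiograph <- function(volume, nodules = list(), config = sim_config(),
                            case_id = "case") {
  stopifnot(inherits(volume, "ct_volume"), inherits(config, "sim_config"))
  if (config$axis != "AP")
    stop_validation("only the posteroanterior (AP-axis) view is supported")
  mu_clean <- hu_to_mu(volume, config$attenuation)
  clean_proj <- forward_project(mu_clean, volume$spacing, "AP")
  d <- dim(volume$voxels)
  projs <- list()
  for (i in seq_along(nodules)) {
    nd <- nodules[[i]]$nodule
    pos <- nodules[[i]]$position
    grid <- rasterize_mu(nd, volume$spacing, config$intensity)
    projs[[i]] <- project_nodule_at(grid, pos, d, volume$spacing)
  }
  records <- tibble(
    case_id = case_id,
    lesion_id = seq_along(nodules),
    com_x = rep(NA_real_, length(nodules)),
    com_y = rep(NA_real_, length(nodules)),
    diameter_mm = vapply(nodules, function(n) max(n$nodule$extent_mm), 0),
    shape_id = vapply(nodules, function(n) n$nodule$id, "")
  )
  compose_radiograph(clean_proj, projs, records, volume$spacing,
                     config$out_size, case_id = case_id,
                     provenance = list(n_lesions = length(nodules)))
}

# training-mode augmentation draws: lesion count uniform on 1..6, shapes
# uniform with replacement, coronal rotation uniform on [0, 360), per-axis
# extents uniform on [8, 20] mm
draw_training_params <- function(pool_size) {
  n <- sample.int(6L, 1L)
  list(n = n,
       shape_idx = sample.int(pool_size, n, replace = TRUE),
       rotation = runif(n, 0, 360),
       extents = matrix(runif(3 * n, 8, 20), nrow = n))
}

#' Generate one training-style case
#'
#' Inserts between 1 and 6 nodules (uniformly) drawn from the pool with
#' equal probability, each augmented with a uniform coronal rotation and
#' independent per-axis extents in \[8, 20\] mm, at uniform non-overlapping
#' lung positions.
#'
#' @param volume nodule-free [ct_volume()], table removed.
#' @param pool a [nodule_pool()].
#' @param seed integer seed; fixed seed gives identical output.
#' @param lung optional precomputed [segment_lung()] mask.
#' @param config a [sim_config()].
#' @return a `simulated_radiograph`.
#' @export
generate_training_case <- function(volume, pool, seed = 1, lung = NULL,
                                   config = sim_config()) {
  stopifnot(inherits(pool, "nodule_pool"))
  if (is.null(lung)) lung <- segment_lung(volume)
  pars <- with_seed(seed, draw_training_params(length(pool$shapes)))
  nods <- lapply(seq_len(pars$n), function(i)
    augment(pool$shapes[[pars$shape_idx[i]]], rotation_deg = pars$rotation[i],
            target_extent_mm = pars$extents[i, ]))
  pos <- sample_positions(lung, lapply(nods, function(n) n$extent_mm),
                          seed = seed + 1L)
  make_radiograph(volume, Map(function(n, p) list(nodule = n, position = p),
                              nods, pos),
                  config = config)
}

#' Study composition configuration
#'
#' The default composition reproduces the benchmark reader-study set:
#' 201 radiographs from nodule-free scans — 20 with no nodule, 53 with one,
#' 67 with two and 61 with three — and 370 inserted nodules with diameters
#' 8/10/15/20 mm in counts 32/111/120/107. Study-mode nodules are scaled
#' isotropically to their assigned diameter.
#'
#' @param n_per_count named integer vector: radiograph count per
#'   lesion-count class (names are the lesion counts).
#' @param size_counts named integer vector: lesion count per diameter class
#'   (names are diameters in mm).
#' @param out_size output image size.
#' @param unique_healthy_volume generate at most one nodule-free radiograph
#'   per source volume, avoiding duplicate healthy images.
#' @export
study_config <- function(n_per_count = c("0" = 20, "1" = 53, "2" = 67,
                                         "3" = 61),
                         size_counts = c("8" = 32, "10" = 111, "15" = 120,
                                         "20" = 107),
                         out_size = 512, unique_healthy_volume = TRUE) {
  n_per_count <- setNames(as.integer(n_per_count), names(n_per_count))
  size_counts <- setNames(as.integer(size_counts), names(size_counts))
  if (is.null(names(n_per_count)) || anyNA(as.integer(names(n_per_count))))
    stop_validation("n_per_count must be named by lesion count")
  if (is.null(names(size_counts)) || anyNA(as.numeric(names(size_counts))))
    stop_validation("size_counts must be named by diameter (mm)")
  slots <- sum(as.integer(names(n_per_count)) * n_per_count)
  if (slots != sum(size_counts))
    stop_validation(sprintf(
      "inconsistent composition: %d lesion slots vs %d sizes",
      slots, sum(size_counts)))
  structure(list(n_per_count = n_per_count, size_counts = size_counts,
                 out_size = as.integer(out_size),
                 unique_healthy_volume = unique_healthy_volume),
            class = "study_config")
}

#' Generate a reader-study set
#'
#' Generates the configured number of radiographs per lesion-count class
#' from a pool of nodule-free volumes. Lesion diameters are a seeded random
#' permutation of the configured size multiset assigned to lesion slots in
#' case order; nodules are drawn from the shape pool with equal
#' probability, rotated uniformly in the coronal plane and scaled
#' isotropically to their assigned diameter. Source volumes are cycled;
#' nodule-free cases use distinct volumes when
#' `unique_healthy_volume = TRUE`. Per-case lesion weights are equal and
#' sum to one.
#'
#' @param volumes named list of nodule-free [ct_volume()]s (tables are
#'   removed here if present).
#' @param config a [study_config()].
#' @param pool a [nodule_pool()].
#' @param seed integer seed; the whole study is a pure function of
#'   (volumes, config, pool, seed).
#' @param sim a [sim_config()]; its `out_size` is overridden by the study
#'   config.
#' @param keep_images keep the rendered `simulated_radiograph` objects in
#'   the return value (set `FALSE` for manifest-only runs).
#' @param out_dir optional directory; when given, images (16-bit PNG),
#'   ground-truth masks and the manifest CSVs plus a config echo are
#'   written there.
#' @return object of class `study_set`: `manifest` (list of `cases` and
#'   `lesions` tibbles), `images` (list or `NULL`), `seed`, `config`.
#' @export
generate_study <- function(volumes, config = study_config(),
                           pool = nodule_pool(), seed = 1,
                           sim = sim_config(), keep_images = TRUE,
                           out_dir = NULL) {
  stopifnot(inherits(config, "study_config"), inherits(pool, "nodule_pool"))
  if (!length(volumes)) stop_validation("need at least one source volume")
  if (is.null(names(volumes)))
    names(volumes) <- sprintf("vol_%03d", seq_along(volumes))
  sim$out_size <- config$out_size
  counts <- as.integer(names(config$n_per_count))
  n_cases <- sum(config$n_per_count)
  lesion_counts <- rep(counts, config$n_per_count)
  n_healthy <- sum(lesion_counts == 0)
  if (config$unique_healthy_volume && n_healthy > length(volumes))
    stop_validation(sprintf(
      "%d nodule-free cases requested but only %d source volumes",
      n_healthy, length(volumes)))
  sizes_all <- rep(as.numeric(names(config$size_counts)), config$size_counts)

  # preprocess each volume once
  prepped <- lapply(volumes, function(v)
    withCallingHandlers(remove_table(v),
                        cxrsim_no_table_warning = function(w)
                          invokeRestart("muffleWarning")))
  lungs <- lapply(prepped, segment_lung)
  clean_projs <- lapply(prepped, function(v)
    forward_project(hu_to_mu(v, sim$attenuation), v$spacing, "AP"))

  nv <- length(volumes)
  out <- with_seed(seed, {
    size_perm <- sample(sizes_all)
    # assign volumes: healthy cases get distinct volumes, diseased cycle
    vol_idx <- integer(n_cases)
    healthy <- which(lesion_counts == 0)
    diseased <- which(lesion_counts > 0)
    vol_idx[healthy] <- seq_along(healthy) %% nv + 1L
    vol_idx[diseased] <- (seq_along(diseased) - 1L) %% nv + 1L
    cases <- vector("list", n_cases)
    lesions <- vector("list", n_cases)
    images <- if (keep_images || !is.null(out_dir)) vector("list", n_cases)
    slot <- 0L
    for (ci in seq_len(n_cases)) {
      case_id <- sprintf("case_%03d", ci)
      L <- lesion_counts[ci]
      vi <- vol_idx[ci]
      vol <- prepped[[vi]]
      if (L > 0) {
        dia <- size_perm[slot + seq_len(L)]
        slot <- slot + L
        shape_idx <- sample.int(length(pool$shapes), L, replace = TRUE)
        rot <- runif(L, 0, 360)
        nods <- lapply(seq_len(L), function(i)
          augment(pool$shapes[[shape_idx[i]]], rotation_deg = rot[i],
                  target_extent_mm = dia[i]))
        pos_seed <- sample.int(2^30, 1L)
        pos <- sample_positions(lungs[[vi]],
                                lapply(nods, function(n) n$extent_mm),
                                seed = pos_seed)
        projs <- lapply(seq_len(L), function(i)
          project_nodule_at(rasterize_mu(nods[[i]], vol$spacing,
                                         sim$intensity),
                            pos[[i]], dim(vol$voxels), vol$spacing))
        rec <- tibble(case_id = case_id, lesion_id = seq_len(L),
                      com_x = NA_real_, com_y = NA_real_,
                      diameter_mm = dia,
                      shape_id = vapply(nods, function(n) n$id, ""))
      } else {
        projs <- list()
        rec <- tibble(case_id = character(), lesion_id = integer(),
                      com_x = numeric(), com_y = numeric(),
                      diameter_mm = numeric(), shape_id = character())
      }
      sr <- compose_radiograph(clean_projs[[vi]], projs, rec, vol$spacing,
                               sim$out_size, case_id = case_id,
                               provenance = list(volume = names(volumes)[vi],
                                                 seed = seed))
      cases[[ci]] <- tibble(case_id = case_id,
                            volume_id = names(volumes)[vi],
                            n_lesions = L,
                            lesion_weight = if (L > 0) 1 / L else NA_real_)
      if (L > 0) {
        r <- sr$records
        r$weight <- 1 / L
        lesions[[ci]] <- r
      }
      if (!is.null(images)) images[[ci]] <- sr
    }
    list(cases = bind_rows(cases), lesions = bind_rows(lesions),
         images = images)
  })
  manifest <- list(cases = out$cases, lesions = out$lesions)
  study <- structure(list(manifest = manifest,
                          images = if (keep_images) out$images,
                          seed = seed, config = config),
                     class = "study_set")
  if (!is.null(out_dir)) write_study(study, out_dir, images = out$images)
  study
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("<study_set> %d radiographs, %d lesions (seed %d)\n",
              nrow(x$manifest$cases), nrow(x$manifest$lesions), x$seed))
  tab <- table(x$manifest$cases$n_lesions)
  cat("  lesion-count classes:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  if (nrow(x$manifest$lesions)) {
    st <- table(x$manifest$lesions$diameter_mm)
    cat("  size histogram (mm):",
        paste(sprintf("%s:%d", names(st), st), collapse = " "), "\n")
  }
  invisible(x)
}

# write manifest CSVs, config echo and (optionally) images/masks
write_study <- function(study, out_dir, images = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(study$manifest$cases, file.path(out_dir, "cases.csv"),
            row.names = FALSE)
  write.csv(study$manifest$lesions, file.path(out_dir, "lesions.csv"),
            row.names = FALSE)
  cfg <- study$config
  yaml::write_yaml(list(seed = study$seed,
                        n_per_count = as.list(cfg$n_per_count),
                        size_counts = as.list(cfg$size_counts),
                        out_size = cfg$out_size,
                        unique_healthy_volume = cfg$unique_healthy_volume),
                   file.path(out_dir, "study_config.yaml"))
  if (!is.null(images)) {
    img_dir <- file.path(out_dir, "images")
    mask_dir <- file.path(out_dir, "masks")
    dir.create(img_dir, showWarnings = FALSE)
    dir.create(mask_dir, showWarnings = FALSE)
    for (sr in images) {
      export_radiograph(sr$image, file.path(img_dir,
                                            paste0(sr$case_id, ".png")))
      for (i in seq_along(sr$gt_masks))
        export_mask(sr$gt_masks[[i]],
                    file.path(mask_dir,
                              sprintf("%s_lesion_%02d.png", sr$case_id, i)))
    }
  }
  invisible(NULL)
}

#' Load a study manifest written by [generate_study()]
#'
#' @param dir directory containing `cases.csv` and `lesions.csv`.
#' @return list with `cases` and `lesions` tibbles.
#' @export
read_study_manifest <- function(dir) {
  cases <- file.path(dir, "cases.csv")
  lesions <- file.path(dir, "lesions.csv")
  if (!file.exists(cases) || !file.exists(lesions))
    stop_io(paste("no study manifest in", dir))
  list(cases = as_tibble(read.csv(cases, stringsAsFactors = FALSE,
                                  colClasses = c(case_id = "character"))),
       lesions = as_tibble(read.csv(lesions, stringsAsFactors = FALSE,
                                    colClasses = c(case_id = "character"))))
}
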