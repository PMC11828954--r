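#' Configuration for the synthetic paired-modality cohort generator
#'
#' Describes a desk-scale cohort emulating the statistical shape of a paired
#' neuroimaging dataset: a subjects-by-regions volumetric table (138 brain-region
#' volumes) paired with left/right lateral 2D projection images, binary
#' labels (`cn` = cognitively normal, `ad` = disease), and a train/test
#' split. Class effects are split between the modalities: a designated set of
#' "affected" regions is shifted between classes in the table, and a fixed
#' circular patch of the images carries a class-shifted mean intensity. A
#' configurable `ambiguous_fraction` of subjects carries *no* class signal in
#' the table (their volumes are drawn from the class-independent baseline),
#' so for them only the image modality separates the classes - the structure
#' an uncertainty gate must exploit.
#'
#' @param n_subjects Cohort size (default 408).
#' @param n_regions Number of volumetric features (default 138).
#' @param image_size Side length in pixels of the square images (default 64
#'   for desk-scale speed; 224 matches full-size surface projections).
#' @param class_balance Proportion of `ad` subjects (default 0.5).
#' @param delta_t Tabular effect size: standardized mean shift (in units of
#'   the log-volume noise SD) between classes in each affected region.
#' @param delta_i Image effect size: patch intensity shift in units of the
#'   per-pixel image noise SD.
#' @param sigma_log SD of log-volumes around their region-specific means.
#' @param image_noise_sd Per-pixel Gaussian noise SD on the [0, 1] scale.
#' @param ambiguous_fraction Fraction q of subjects whose tabular features
#'   carry no class signal.
#' @param n_train Training-split size (default 180; the
#'   remainder is the test split).
#' @param n_affected_down,n_affected_up Numbers of regions decreased /
#'   increased in the `ad` class (atrophy-like and ventricle-like effects).
#' @param seed Integer seed; the cohort is bit-reproducible given the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 408,
                         n_regions = 138,
                         image_size = 64,
                         class_balance = 0.5,
                         delta_t = 1.5,
                         delta_i = 1.5,
                         sigma_log = 0.15,
                         image_noise_sd = 0.08,
                         ambiguous_fraction = 0.3,
                         n_train = 180,
                         n_affected_down = 10,
                         n_affected_up = 4,
                         seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_regions = n_regions,
              image_size = image_size, class_balance = class_balance,
              delta_t = delta_t, delta_i = delta_i, sigma_log = sigma_log,
              image_noise_sd = image_noise_sd,
              ambiguous_fraction = ambiguous_fraction,
              n_train = n_train,
              n_affected_down = n_affected_down,
              n_affected_up = n_affected_up, seed = seed)
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1) {
    stop("`ambiguous_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (n_train >= n_subjects) stop("`n_train` must be < `n_subjects`", call. = FALSE)
  if (n_subjects < 4 || n_regions < 1 || image_size < 8) {
    stop("invalid cohort sizes", call. = FALSE)
  }
  if (n_affected_down + n_affected_up > n_regions) {
    stop("more affected regions than regions", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

region_names <- function(n) sprintf("region_%03d", seq_len(n))

#' Generate a synthetic paired-modality cohort
#'
#' Draws a cohort under a [synth_config()]. Baseline region volumes are
#' log-normal (volumes are positive and right-skewed); class effects are
#' applied on the log scale as `+/- delta_t * sigma_log / 2` per class in the
#' affected regions (decreased in `ad` for the atrophy-like set, increased
#' for the ventricle-like set). Every subject's images carry the class-
#' shifted patch; ambiguous subjects additionally have their tabular volumes
#' drawn from the baseline with no class shift. Pixel intensities are
#' quantized to 8 bits so that in-memory images round-trip PNG files exactly.
#'
#' @param config A [synth_config()].
#' @return A tibble with one row per subject: `subject_id`, `label` (factor
#'   `cn`/`ad`), `split` (`train`/`test`), `is_ambiguous`, the region columns
#'   `region_001` ... , and list-columns `image_left`, `image_right` (H x W x
#'   3 arrays in [0, 1]). Ground-truth metadata (affected region indices,
#'   patch geometry, config) is attached as `attr(, "meta")`.
#' @examples
#' cohort <- generate_cohort(synth_config(n_subjects = 24, n_train = 12))
#' dplyr::count(cohort, label, split)
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  if (cfg$ambiguous_fraction > 0 && cfg$ambiguous_fraction * cfg$n_subjects < 1) {
    warning("ambiguous_fraction * n_subjects < 1: no ambiguous subjects generated")
  }
  withr::with_seed(cfg$seed, {
    n <- cfg$n_subjects
    R <- cfg$n_regions
    # region-specific baseline log-volumes (arbitrary units, ~0.5-60)
    m <- stats::runif(R, log(0.5), log(60))
    affected <- sample.int(R, cfg$n_affected_down + cfg$n_affected_up)
    aff_down <- sort(affected[seq_len(cfg$n_affected_down)])
    aff_up <- sort(affected[cfg$n_affected_down + seq_len(cfg$n_affected_up)])

    n_ad <- round(n * cfg$class_balance)
    label <- c(rep("ad", n_ad), rep("cn", n - n_ad))[sample.int(n)]
    is_amb <- seq_len(n) %in% sample.int(n, round(cfg$ambiguous_fraction * n))

    # class shift on the log scale, halved and mirrored so the between-class
    # difference is delta_t * sigma_log in every affected region
    half <- cfg$delta_t * cfg$sigma_log / 2
    sgn <- ifelse(label == "ad", 1, -1)          # +1 for ad, -1 for cn
    shift <- matrix(0, n, R)
    shift[, aff_down] <- -sgn * half             # ad decreased
    shift[, aff_up] <- sgn * half                # ad increased
    shift[is_amb, ] <- 0
    logx <- matrix(m, n, R, byrow = TRUE) + shift +
      matrix(stats::rnorm(n * R, 0, cfg$sigma_log), n, R)
    X <- exp(logx)
    colnames(X) <- region_names(R)

    # images: grey background, one circular class-shifted patch on the red
    # channel of each lateral view, i.i.d. pixel noise, 8-bit quantization
    sz <- cfg$image_size
    patch <- list(left = c(cx = 0.35 * sz, cy = 0.45 * sz, r = sz / 6),
                  right = c(cx = 0.65 * sz, cy = 0.45 * sz, r = sz / 6))
    mask_for <- function(p) {
      g <- expand.grid(r = seq_len(sz), c = seq_len(sz))
      matrix((g$c - p["cx"])^2 + (g$r - p["cy"])^2 <= p["r"]^2, sz, sz)
    }
    masks <- lapply(patch, mask_for)
    amp <- cfg$delta_i * cfg$image_noise_sd / 2
    draw_image <- function(side, s) {
      img <- array(0.5, c(sz, sz, 3))
      img[, , 1][masks[[side]]] <- 0.5 + s * amp
      img <- img + array(stats::rnorm(sz * sz * 3, 0, cfg$image_noise_sd), c(sz, sz, 3))
      img <- pmin(pmax(img, 0), 1)
      round(img * 255) / 255
    }
    image_left <- lapply(seq_len(n), function(i) draw_image("left", sgn[i]))
    image_right <- lapply(seq_len(n), function(i) draw_image("right", sgn[i]))

    # stratified train/test split
    split <- rep("test", n)
    for (cl in c("cn", "ad")) {
      idx <- which(label == cl)
      k <- round(cfg$n_train * length(idx) / n)
      split[sample(idx, k)] <- "train"
    }
    # exact train size (rounding can be off by one)
    excess <- sum(split == "train") - cfg$n_train
    if (excess > 0) split[sample(which(split == "train"), excess)] <- "test"
    if (excess < 0) split[sample(which(split == "test"), -excess)] <- "train"

    cohort <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      label = factor(label, levels = c("cn", "ad")),
      split = split,
      is_ambiguous = is_amb
    )
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(X))
    cohort$image_left <- image_left
    cohort$image_right <- image_right
    attr(cohort, "meta") <- list(
      config = unclass(cfg),
      affected_down = aff_down,
      affected_up = aff_up,
      patch = patch
    )
    cohort
  })
}

#' Write / read a cohort directory
#'
#' `write_cohort()` serializes a cohort as a plain-text/PNG directory:
#' `tabular.csv` (columns `subject_id`, `label`, `split`, `region_*`),
#' `images/<subject_id>_left.png` and `_right.png`, and `metadata.json`
#' (generator config, affected-region indices, patch geometry, per-subject
#' ambiguity flags). `read_cohort()` reconstructs the cohort tibble;
#' `read_cohort(write_cohort(x))` reproduces `x` (pixels bit-exact, volumes
#' to full double precision).
#'
#' @param cohort A cohort tibble from [generate_cohort()] or [read_cohort()].
#' @param dir Directory path; created if missing.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   the cohort tibble with metadata attached.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  reg <- grep("^region_\\d+$", names(cohort), value = TRUE)
  tab <- data.frame(subject_id = cohort$subject_id,
                    label = as.character(cohort$label),
                    split = cohort$split,
                    cohort[reg], check.names = FALSE)
  utils::write.csv(tab, file.path(dir, "tabular.csv"), row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    png::writePNG(cohort$image_left[[i]],
                  file.path(dir, "images", paste0(cohort$subject_id[i], "_left.png")))
    png::writePNG(cohort$image_right[[i]],
                  file.path(dir, "images", paste0(cohort$subject_id[i], "_right.png")))
  }
  meta <- attr(cohort, "meta")
  meta$is_ambiguous <- cohort$is_ambiguous
  meta$subject_id <- cohort$subject_id
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tab_path <- file.path(dir, "tabular.csv")
  meta_path <- file.path(dir, "metadata.json")
  if (!file.exists(tab_path)) stop("cohort file not found: ", tab_path, call. = FALSE)
  if (!file.exists(meta_path)) stop("cohort file not found: ", meta_path, call. = FALSE)
  tab <- utils::read.csv(tab_path, check.names = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cohort <- tibble::as_tibble(tab)
  cohort$label <- factor(cohort$label, levels = c("cn", "ad"))
  amb <- meta$is_ambiguous[match(cohort$subject_id, meta$subject_id)]
  cohort <- dplyr::relocate(
    dplyr::mutate(cohort, is_ambiguous = amb),
    "subject_id", "label", "split", "is_ambiguous")
  read_img <- function(path) {
    if (!file.exists(path)) stop("cohort image not found: ", path, call. = FALSE)
    img <- png::readPNG(path)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  }
  cohort$image_left <- lapply(cohort$subject_id, function(id)
    read_img(file.path(dir, "images", paste0(id, "_left.png"))))
  cohort$image_right <- lapply(cohort$subject_id, function(id)
    read_img(file.path(dir, "images", paste0(id, "_right.png"))))
  meta$is_ambiguous <- NULL
  meta$subject_id <- NULL
  if (!is.null(meta$config)) meta$config <- do.call(synth_config, meta$config)
  attr(cohort, "meta") <- meta
  cohort
}

#' A tiny fixed cohort for examples and tests
#'
#' A 24-subject cohort (12 train / 12 test) at reduced image size, generated
#' deterministically; convenient as a fast fixture.
#'
#' @param seed Integer seed.
#' @return A cohort tibble.
#' @export
cohort_fixture <- function(seed = 20260924) {
  generate_cohort(synth_config(n_subjects = 24, n_train = 12, image_size = 32,
                               seed = seed))
}
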