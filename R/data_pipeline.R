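# Labeled multi-domain image datasets: container, disk format (PNG images +
# CSV manifest with columns path,class,domain), preprocessing (resize,
# channel replication, normalization to [-1, 1]), stratified splits, and the
# balanced mixed-domain batch stream used by adaptation training.

#' Labeled multi-domain image set
#'
#' The central data container: images in a common value range with per-item
#' class and domain labels.
#'
#' @param images numeric array `(H, W, C, N)`, values in `[-1, 1]`.
#' @param class_labels integer vector, values in `{0..n_classes-1}`.
#' @param domain_labels integer vector, values in `{0..n_domains-1}`.
#' @param n_classes,n_domains declared label ranges (defaults: inferred).
#' @param manifest optional tibble recording per-item provenance.
#' @return an `image_set`.
#' @export
image_set <- function(images, class_labels, domain_labels,
                      n_classes = NULL, n_domains = NULL, manifest = NULL) {
  if (length(dim(images)) != 4) stop("images must be a (H, W, C, N) array")
  n <- dim(images)[4]
  if (length(class_labels) != n || length(domain_labels) != n) {
    stop("images, class_labels and domain_labels must have equal length")
  }
  if (n > 0) {
    rng <- range(images)
    if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9) {
      stop("image values must lie in [-1, 1]; observed range [",
           signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
    }
  }
  structure(list(images = images,
                 class_labels = as.integer(class_labels),
                 domain_labels = as.integer(domain_labels),
                 n_classes = n_classes %||% (max(class_labels) + 1L),
                 n_domains = n_domains %||% (max(domain_labels) + 1L),
                 manifest = manifest),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images)
  cat("<image_set: ", d[4], " images ", d[1], "x", d[2], "x", d[3],
      ", ", x$n_classes, " classes, ", x$n_domains, " domains>\n", sep = "")
  invisible(x)
}

#' @export
length.image_set <- function(x) dim(x$images)[4]

#' Subset an image set by item index
#' @param set an [image_set()].
#' @param idx integer indices of the items to keep.
#' @return an [image_set()].
#' @export
subset_items <- function(set, idx) {
  image_set(set$images[, , , idx, drop = FALSE],
            set$class_labels[idx], set$domain_labels[idx],
            n_classes = set$n_classes, n_domains = set$n_domains,
            manifest = if (!is.null(set$manifest)) set$manifest[idx, ])
}

#' Concatenate image sets (shapes and declared label ranges must agree)
#' @param ... image sets.
#' @return an [image_set()].
#' @export
bind_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "image_set")) {
    sets <- sets[[1]]
  }
  dm <- dim(sets[[1]]$images)[1:3]
  arrs <- lapply(sets, function(s) s$images)
  n <- sum(vapply(arrs, function(a) dim(a)[4], 0))
  out <- array(0, c(dm, n))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[4]
    out[, , , at + seq_len(k)] <- a
    at <- at + k
  }
  image_set(out,
            unlist(lapply(sets, `[[`, "class_labels")),
            unlist(lapply(sets, `[[`, "domain_labels")),
            n_classes = max(vapply(sets, `[[`, 0L, "n_classes")),
            n_domains = max(vapply(sets, `[[`, 0L, "n_domains")))
}

# (H, W, C, N) container layout -> (C, H, W, N) network layout, and back
internal_layout <- function(images) aperm(images, c(3, 1, 2, 4))
container_layout <- function(images) aperm(images, c(2, 3, 1, 4))

#' Normalize pixel values from \[0, 1\] to \[-1, 1\]
#'
#' Centers at 0.5 and scales by 0.5: `(x - 0.5) / 0.5`.
#'
#' @param x numeric array with values in `[0, 1]`.
#' @return array of the same shape with values in `[-1, 1]`.
#' @export
normalize_image <- function(x) {
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("normalize_image expects values in [0, 1]; observed range [",
         signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  (x - 0.5) / 0.5
}

#' Invert [normalize_image()]
#' @param x numeric array with values in `[-1, 1]`.
#' @return array with values in `[0, 1]`.
#' @export
denormalize_image <- function(x) x * 0.5 + 0.5

#' Resize a single image
#'
#' Nearest-neighbour maps output pixel `(i, j)` (0-based) to input pixel
#' `(floor(i * H_in / H_out), floor(j * W_in / W_out))`. Bilinear uses
#' half-pixel-centre sampling with edge clamping.
#'
#' @param img `(H, W, C)` array.
#' @param size target `(H, W)`.
#' @param interp `"nearest"` or `"bilinear"`.
#' @return `(H_out, W_out, C)` array.
#' @export
resize_image <- function(img, size, interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  hin <- dim(img)[1]; win <- dim(img)[2]; C <- dim(img)[3]
  ho <- size[1]; wo <- size[2]
  if (interp == "nearest") {
    ri <- pmin(floor((0:(ho - 1)) * hin / ho), hin - 1) + 1
    ci <- pmin(floor((0:(wo - 1)) * win / wo), win - 1) + 1
    return(img[ri, ci, , drop = FALSE])
  }
  # bilinear, half-pixel centres, clamped at the borders
  sy <- (0:(ho - 1) + 0.5) * hin / ho - 0.5
  sx <- (0:(wo - 1) + 0.5) * win / wo - 0.5
  y0 <- pmin(pmax(floor(sy), 0), hin - 1); y1 <- pmin(y0 + 1, hin - 1)
  x0 <- pmin(pmax(floor(sx), 0), win - 1); x1 <- pmin(x0 + 1, win - 1)
  wy <- pmin(pmax(sy - y0, 0), 1); wx <- pmin(pmax(sx - x0, 0), 1)
  out <- array(0, c(ho, wo, C))
  for (c in seq_len(C)) {
    ch <- img[, , c]
    a <- ch[cbind(rep(y0 + 1, wo), rep(x0 + 1, each = ho))]
    b <- ch[cbind(rep(y0 + 1, wo), rep(x1 + 1, each = ho))]
    d <- ch[cbind(rep(y1 + 1, wo), rep(x0 + 1, each = ho))]
    e <- ch[cbind(rep(y1 + 1, wo), rep(x1 + 1, each = ho))]
    wym <- rep(wy, wo); wxm <- rep(wx, each = ho)
    out[, , c] <- (1 - wym) * ((1 - wxm) * a + wxm * b) +
      wym * ((1 - wxm) * d + wxm * e)
  }
  out
}

#' Load a labeled image dataset from a CSV manifest
#'
#' The manifest must have a header with columns `path,class,domain`; paths
#' are resolved relative to the manifest's directory. Images are resized with
#' the requested interpolation, grayscale images are replicated to 3
#' channels, and pixel values are normalized to `[-1, 1]` via
#' [normalize_image()].
#'
#' @param manifest_path path to the CSV manifest.
#' @param image_size target `(H, W)`.
#' @param interp `"nearest"` (digit scale) or `"bilinear"` (radiograph scale).
#' @param channels output channel count (grayscale inputs are replicated).
#' @return an [image_set()].
#' @export
load_dataset <- function(manifest_path, image_size = c(32, 32),
                         interp = c("nearest", "bilinear"), channels = 3) {
  interp <- match.arg(interp)
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  req <- c("path", "class", "domain")
  if (!all(req %in% names(man))) {
    stop("manifest must have columns path,class,domain; found: ",
         paste(names(man), collapse = ","))
  }
  if (any(is.na(man$class)) || any(man$class < 0) ||
      any(man$class != floor(man$class))) {
    stop("manifest rejected: class labels must be non-negative integers")
  }
  if (any(is.na(man$domain)) || any(man$domain < 0) ||
      any(man$domain != floor(man$domain))) {
    stop("manifest rejected: domain labels must be non-negative integers")
  }
  base <- dirname(manifest_path)
  n <- nrow(man)
  out <- array(0, c(image_size[1], image_size[2], channels, n))
  for (i in seq_len(n)) {
    f <- man$path[i]
    if (!file.exists(f)) f <- file.path(base, man$path[i])
    if (!file.exists(f)) stop("missing image file for manifest row ", i, ": ",
                              man$path[i])
    img <- png::readPNG(f)
    if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1)
    if (dim(img)[3] > channels) img <- img[, , seq_len(channels), drop = FALSE]
    img <- resize_image(img, image_size, interp)
    if (dim(img)[3] < channels) {
      img <- array(rep(img[, , 1], channels),
                   c(image_size[1], image_size[2], channels))
    }
    out[, , , i] <- img
  }
  image_set(normalize_image(out), man$class, man$domain,
            manifest = tibble::as_tibble(man))
}

#' Write an image set as PNG files plus a CSV manifest
#'
#' Pixel values are mapped back to `[0, 1]` and quantized to 8 bits by the
#' PNG encoder; labels round-trip exactly.
#'
#' @param set an [image_set()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix for the PNGs.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(set, dir, prefix = "img") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(set)
  paths <- sprintf("%s_%05d.png", prefix, seq_len(n))
  for (i in seq_len(n)) {
    img <- denormalize_image(set$images[, , , i])
    png::writePNG(pmin(pmax(img, 0), 1), file.path(dir, paths[i]))
  }
  man <- tibble::tibble(path = paths, class = set$class_labels,
                        domain = set$domain_labels)
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(man, mpath)
  invisible(mpath)
}

#' Stratified train/validation/test split
#'
#' Deterministic for a fixed seed. Items are shuffled and allocated within
#' each (class, domain) stratum by largest-remainder apportionment, so each
#' split's per-class counts stay within one item of proportionality.
#'
#' @param set an [image_set()].
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed for the shuffle.
#' @return named list of image sets: `train`, `val`, `test`.
#' @export
split_dataset <- function(set, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  if (length(set) == 0) stop("cannot split an empty set")
  stopifnot(length(fractions) == 3)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  strata <- split(seq_len(length(set)),
                  paste(set$class_labels, set$domain_labels))
  small <- vapply(strata, length, 0L) < 3
  if (any(small)) {
    warning("strata with fewer than 3 items (", sum(small),
            "); best-effort assignment")
  }
  assign_idx <- list(integer(0), integer(0), integer(0))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  for (s in strata) {
    s <- s[sample.int(length(s))]
    m <- length(s)
    base <- floor(fractions * m)
    rem <- fractions * m - base
    extra <- m - sum(base)
    if (extra > 0) {
      give <- order(rem, decreasing = TRUE)[seq_len(extra)]
      base[give] <- base[give] + 1
    }
    cuts <- cumsum(base)
    assign_idx[[1]] <- c(assign_idx[[1]], s[seq_len(base[1])])
    if (base[2] > 0) assign_idx[[2]] <- c(assign_idx[[2]], s[(cuts[1] + 1):cuts[2]])
    if (base[3] > 0) assign_idx[[3]] <- c(assign_idx[[3]], s[(cuts[2] + 1):cuts[3]])
  }
  list(train = subset_items(set, sort(assign_idx[[1]])),
       val = subset_items(set, sort(assign_idx[[2]])),
       test = subset_items(set, sort(assign_idx[[3]])))
}

#' Batch plan for mixed-domain training batches
#'
#' @param batch_size total batch size B.
#' @param even_domain_split when `TRUE` each batch holds `floor(B/2)` source
#'   and `ceiling(B/2)` target items.
#' @param balance_by_class when `TRUE` the source items in each batch are
#'   class-balanced up to remainder.
#' @param seed integer seed for the sampling stream.
#' @return a `batch_plan` list.
#' @export
batch_plan <- function(batch_size = 32, even_domain_split = TRUE,
                       balance_by_class = FALSE, seed = 1) {
  if (even_domain_split && batch_size < 2) {
    stop("batch_size must be at least 2 when even_domain_split is set")
  }
  structure(list(batch_size = as.integer(batch_size),
                 even_domain_split = even_domain_split,
                 balance_by_class = balance_by_class, seed = seed),
            class = "batch_plan")
}

#' Unbounded stream of mixed source/target batches
#'
#' Samples with replacement across epochs (training is iteration-counted).
#' Returns a closure; each call yields a list with the batch images in
#' network layout `(C, H, W, B)`, class labels (`NA` for target items),
#' domain labels, and an `is_source` flag.
#'
#' @param source,target image sets (target class labels are never exposed).
#' @param plan a [batch_plan()].
#' @return function() -> batch list.
#' @export
iterate_batches <- function(source, target, plan) {
  if (length(source) == 0 || length(target) == 0) {
    stop("both source and target sets must be nonempty")
  }
  xs <- internal_layout(source$images)
  xt <- internal_layout(target$images)
  ys <- source$class_labels
  by_class <- split(seq_along(ys), ys)
  rng <- .rng_stream(plan$seed)
  B <- plan$batch_size
  ns <- if (plan$even_domain_split) B %/% 2L else B
  nt <- if (plan$even_domain_split) B - ns else 0L
  function() {
    rng$activate()
    on.exit(rng$save())
    if (plan$balance_by_class) {
      ks <- length(by_class)
      per <- rep(ns %/% ks, ks)
      extra <- ns - sum(per)
      if (extra > 0) {
        bump <- sample.int(ks, extra)
        per[bump] <- per[bump] + 1
      }
      si <- unlist(mapply(function(ix, k) ix[sample.int(length(ix), k, replace = TRUE)],
                          by_class, per, SIMPLIFY = FALSE))
      si <- si[sample.int(length(si))]
    } else {
      si <- sample.int(dim(xs)[4], ns, replace = TRUE)
    }
    ti <- if (nt > 0) sample.int(dim(xt)[4], nt, replace = TRUE) else integer(0)
    dm <- dim(xs)[1:3]
    x <- array(0, c(dm, ns + nt))
    if (ns > 0) x[, , , seq_len(ns)] <- xs[, , , si, drop = FALSE]
    if (nt > 0) x[, , , ns + seq_len(nt)] <- xt[, , , ti, drop = FALSE]
    list(x = x,
         class = c(ys[si], rep(NA_integer_, nt)),
         domain = c(source$domain_labels[si], target$domain_labels[ti]),
         is_source = rep(c(TRUE, FALSE), c(ns, nt)))
  }
}

# private RNG stream helpers: keep sampling reproducible without trampling
# the caller's global RNG state
.save_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
.rng_stream <- function(seed) {
  state <- local({ old <- .save_rng(); set.seed(seed)
                   s <- get(".Random.seed", globalenv()); .restore_rng(old); s })
  outer_state <- NULL
  list(
    activate = function() {
      outer_state <<- .save_rng()
      assign(".Random.seed", state, globalenv())
    },
    save = function() {
      state <<- get(".Random.seed", globalenv())
      .restore_rng(outer_state)
    }
  )
}
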