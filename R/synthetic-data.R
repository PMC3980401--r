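#' Specification of a synthetic layered-image benchmark
#'
#' The generator emulates the statistical structure the annotation method
#' assumes: an image is a stack of horizontal tissue-like bands (three
#' layers with distinct base colours, mirroring epidermis / dermis /
#' subcutaneous fat) and every annotation term corresponds to a texture
#' motif painted into one local patch of a random band — so the image-level
#' label is the OR over its patches' term bits, exactly the MIL assumption.
#' Motifs differ in dominant orientation, scale and colour so that the DWT9
#' sub-band energies and LUV means separate them by construction.
#'
#' @param n_images number of images (default 80).
#' @param image_size c(width, height) in pixels (default 64 x 48: the same
#'   4:3 aspect as the 200 x 150 processing convention, at desk scale).
#' @param n_terms number of annotation terms, at most the motif-catalogue
#'   size (default 4).
#' @param term_prevalence per-term positive probability (default 0.5 each).
#' @param noise_sd Gaussian pixel noise standard deviation (default 0.02).
#' @param patch_size c(width, height) of a motif patch (default 12 x 12;
#'   must fit inside one band).
#' @param seed integer seed; the whole image set is reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_images = 80L, image_size = c(64L, 48L),
                           n_terms = 4L, term_prevalence = rep(0.5, n_terms),
                           noise_sd = 0.02, patch_size = c(12L, 12L),
                           seed = 1L) {
  stopifnot(n_terms >= 1L, n_terms <= 4L,
            length(term_prevalence) == n_terms,
            all(term_prevalence >= 0 & term_prevalence <= 1))
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 n_terms = as.integer(n_terms),
                 term_prevalence = term_prevalence,
                 noise_sd = noise_sd,
                 patch_size = as.integer(patch_size),
                 n_layers = 3L,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# band base colours (R, G, B on [0,1]): pink epidermis, pale dermis, cream fat
band_colours <- function() {
  rbind(c(0.80, 0.55, 0.62),
        c(0.91, 0.78, 0.84),
        c(0.95, 0.92, 0.80))
}

# motif catalogue: base colour + texture type/amplitude. Orientation/scale
# separate the motifs in the Haar sub-bands: vertical stripes load HL,
# horizontal stripes load LH, a checkerboard loads HH, and the solid blob
# is separated by its LUV means alone.
motif_catalogue <- function() {
  list(
    t1 = list(colour = c(0.25, 0.45, 0.75), texture = "vstripe", amp = 0.12),
    t2 = list(colour = c(0.30, 0.70, 0.40), texture = "hstripe", amp = 0.12),
    t3 = list(colour = c(0.85, 0.75, 0.25), texture = "checker", amp = 0.12),
    t4 = list(colour = c(0.55, 0.25, 0.60), texture = "solid",   amp = 0))
}

paint_motif <- function(px, motif, r0, c0, h, w) {
  rows <- r0:(r0 + h - 1L); cols <- c0:(c0 + w - 1L)
  base <- motif$colour
  rr <- outer(rows, rep(1L, w)); cc <- outer(rep(1L, h), cols)
  mod <- switch(motif$texture,
                vstripe = (cc %% 2L) * 2 - 1,
                hstripe = (rr %% 2L) * 2 - 1,
                checker = ((rr + cc) %% 2L) * 2 - 1,
                solid = matrix(0, h, w))
  for (ch in 1:3)
    px[rows, cols, ch] <- pmin(pmax(base[ch] + motif$amp * mod, 0.02), 0.98)
  px
}

#' Generate a synthetic layered image set with ground truth
#'
#' Each image is three horizontal colour bands plus, for every sampled
#' positive term, one motif patch painted into a randomly chosen free slot
#' (two slots per band, sampled without replacement, so patches never
#' overlap), followed by Gaussian pixel noise. Returns the images, the
#' image-level annotation matrix and the patch-level term map; the
#' annotation bit is by construction the OR of the patch bits.
#'
#' @param spec a [synthetic_spec].
#' @return list with `images` (list of [raster_image]), `annotation`
#'   (an [annotation_matrix]) and `patches` (per-image list of term
#'   patch rectangles).
#' @export
generate_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  W <- spec$image_size[1L]; H <- spec$image_size[2L]
  band_h <- H %/% spec$n_layers
  pw <- spec$patch_size[1L]; ph <- spec$patch_size[2L]
  if (ph > band_h - 2L || pw > W %/% 2L - 2L)
    stop(sprintf("motif patch (%d x %d) does not fit inside a band (%d x %d)",
                 pw, ph, W %/% 2L, band_h))
  cols <- band_colours()
  motifs <- motif_catalogue()[seq_len(spec$n_terms)]
  terms <- names(motifs)
  set.seed(spec$seed)
  ann <- matrix(0L, spec$n_images, spec$n_terms,
                dimnames = list(sprintf("img%03d", seq_len(spec$n_images)),
                                terms))
  images <- vector("list", spec$n_images)
  patches <- vector("list", spec$n_images)
  for (i in seq_len(spec$n_images)) {
    px <- array(0, c(H, W, 3L))
    for (b in seq_len(spec$n_layers)) {
      rows <- ((b - 1L) * band_h + 1L):(if (b == spec$n_layers) H
                                        else b * band_h)
      for (ch in 1:3) px[rows, , ch] <- cols[b, ch]
    }
    pos <- which(stats::runif(spec$n_terms) < spec$term_prevalence)
    ann[i, pos] <- 1L
    # free slots: 2 per band (left/right half), sampled without replacement
    slots <- expand.grid(band = seq_len(spec$n_layers), half = 1:2)
    slot_idx <- sample(nrow(slots), length(pos))
    pmap <- list()
    for (k in seq_along(pos)) {
      sl <- slots[slot_idx[k], ]
      rmax <- band_h - ph; cmax <- W %/% 2L - pw
      r0 <- (sl$band - 1L) * band_h + 1L + sample.int(max(rmax, 1L), 1L) - 1L
      c0 <- (sl$half - 1L) * (W %/% 2L) + 1L + sample.int(max(cmax, 1L), 1L) - 1L
      px <- paint_motif(px, motifs[[pos[k]]], r0, c0, ph, pw)
      pmap[[terms[pos[k]]]] <- c(row = r0, col = c0, height = ph, width = pw)
    }
    px <- px + array(stats::rnorm(length(px), sd = spec$noise_sd), dim(px))
    px <- pmin(pmax(px, 0.001), 1) # keep clear of pure black (= padding)
    images[[i]] <- raster_image(px, id = rownames(ann)[i])
    patches[[i]] <- pmap
  }
  list(images = images,
       annotation = annotation_matrix(ann, rownames(ann), terms),
       patches = patches)
}

#' Generate bag-level MIL benchmark data
#'
#' A direct sampler of the MIL assumption for learner tests, skipping the
#' image pipeline: negative-bag instances are drawn from N(0, I); in
#' positive bags each instance is independently replaced, with probability
#' `witness_rate`, by a draw from N(mu, I) with `||mu|| = separation`
#' (rejection sampling guarantees at least one witness per positive bag).
#'
#' @param n_pos,n_neg number of positive / negative bags.
#' @param dim instance dimension (default 9, matching DWT9).
#' @param separation Euclidean distance between the two instance
#'   distributions' means (default 6).
#' @param witness_rate probability an instance of a positive bag is a
#'   witness, in (0, 1] (default 0.3).
#' @param instances_range bag sizes drawn uniformly from this range.
#' @param seed integer seed.
#' @param term name of the single term (default "t1").
#' @return A labelled [bag_dataset].
#' @export
generate_bags <- function(n_pos, n_neg, dim = 9L, separation = 6,
                          witness_rate = 0.3, instances_range = c(5L, 10L),
                          seed = 1L, term = "t1") {
  stopifnot(separation >= 0, witness_rate > 0, witness_rate <= 1)
  set.seed(seed)
  mu <- c(separation, rep(0, dim - 1L))
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  ord <- sample.int(n) # interleave classes
  labels <- labels[ord]
  bags <- vector("list", n)
  for (i in seq_len(n)) {
    ni <- sample(instances_range[1L]:instances_range[2L], 1L)
    X <- matrix(stats::rnorm(ni * dim), ni, dim)
    if (labels[i] == 1L) {
      repeat {
        wit <- stats::runif(ni) < witness_rate
        if (any(wit)) break
      }
      X[wit, ] <- X[wit, , drop = FALSE] +
        matrix(mu, sum(wit), dim, byrow = TRUE)
    }
    bags[[i]] <- bag(X, image_id = sprintf("bag%03d", i), scheme = "DWT9")
  }
  ann <- annotation_matrix(matrix(labels, ncol = 1L),
                           vapply(bags, `[[`, "", "image_id"), term)
  bag_dataset(bags, terms = term, annotation = ann)
}

#' Segment and featurize an image set into per-granularity bag datasets
#'
#' The bridge from raw images to the learners: every image is segmented at
#' each requested granularity (one nested recursive-cut pass per image, see
#' [segment_image_multi()]) and its regions turned into a bag of feature
#' vectors.
#'
#' @param images list of [raster_image]s.
#' @param annotation optional [annotation_matrix] aligned with `images`.
#' @param p_values segmentation granularities (default c(8, 10, 12)).
#' @param scheme feature scheme (default `"DWT9"`).
#' @param sigma_i,sigma_x,radius,smooth_sigma pixel-graph parameters; the
#'   defaults (sigma_i = 0.15, radius = 3, affinity smoothing 0.5 px) suit
#'   small textured images: the light smoothing averages fine texture into
#'   its local mean colour so textured patches stay internally coherent,
#'   and the tight colour bandwidth then gives crisp colour boundaries.
#' @return named list of labelled [bag_dataset]s, one per granularity.
#' @export
images_to_bags <- function(images, annotation = NULL, p_values = c(8, 10, 12),
                           scheme = "DWT9", sigma_i = 0.15, sigma_x = 4.0,
                           radius = 3.0, smooth_sigma = 0.5) {
  seg <- lapply(images, segment_image_multi, p_values = p_values,
                sigma_i = sigma_i, sigma_x = sigma_x, radius = radius,
                smooth_sigma = smooth_sigma)
  out <- lapply(paste0("p", sort(unique(as.integer(p_values)))), function(pn) {
    bags <- lapply(seg, function(s) make_bag(s[[pn]], scheme = scheme))
    bag_dataset(bags, terms = colnames(annotation), annotation = annotation,
                meta = list(scheme = scheme, p = pn,
                            graph = list(sigma_i = sigma_i, sigma_x = sigma_x,
                                         radius = radius)))
  })
  names(out) <- paste0("p", sort(unique(as.integer(p_values))))
  out
}
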