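# Shared tiny fixtures: everything is generated in code, at desk scale.

# A thin network variant for engine tests (1/16 width keeps parameter counts
# in the thousands).
tiny_arch <- function(variant = "dfcn4s", n_classes = 4L) {
  build_arch(variant, n_classes = n_classes, width_multiplier = 1 / 16)
}

# Random HU slice resembling a CT value range.
random_hu <- function(h = 64, w = h, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(h * w, mean = -150, sd = 400), h, w)
}

# Random label mask with classes 0..k-1.
random_mask <- function(h = 16, w = h, k = 3, seed = 1) {
  set.seed(seed)
  matrix(sample(0:(k - 1), h * w, replace = TRUE), h, w)
}

# Independent brute-force Dice oracle: literal pixel-set arithmetic on
# index sets, no count pooling shortcuts shared with the implementation.
oracle_dice <- function(pred, ref, class_id) {
  X <- which(as.vector(pred) == class_id)
  Y <- which(as.vector(ref) == class_id)
  if (length(X) + length(Y) == 0) return(NA_real_)
  2 * length(intersect(X, Y)) / (length(X) + length(Y))
}

oracle_global_dice <- function(pred, ref, classes) {
  inter <- 0
  size <- 0
  for (c in classes) {
    X <- which(as.vector(pred) == c)
    Y <- which(as.vector(ref) == c)
    inter <- inter + length(intersect(X, Y))
    size <- size + length(X) + length(Y)
  }
  if (size == 0) return(NA_real_)
  2 * inter / size
}

# Small phantom training world shared by harness tests.
tiny_phantom_cases <- function(n, master_seed, size = 64) {
  generate_phantom_dataset(phantom_config(image_size = c(size, size),
                                          slices_per_case = c(2L, 3L)),
                           n, master_seed = master_seed)$cases
}
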