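# shared fixtures, memoized so expensive objects build once per test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_bundle <- function() {
  fixture("bundle", function() build_template_bundle(n_ref = 10, seed = 100))
}

# a mid-severity posed phantom used across tests
demo_phantom <- function() {
  fixture("demo_phantom", function()
    make_phantom(phantom_spec(mta_severity = c(2, 3), gca_severity = 1.5,
                              fazekas_severity = 2, noise_sd = 5,
                              rng_seed = 7,
                              pose = list(translation_vox = c(1, -1, 0.5),
                                          rotation_deg = c(3, -2, 4)))))
}

# geodesic angle (degrees) between two rotation parameterizations
rotation_error_deg <- function(rot_a, rot_b) {
  Ra <- ctquant:::rotation_matrix(rot_a)
  Rb <- ctquant:::rotation_matrix(rot_b)
  R <- t(Ra) %*% Rb
  acos(min(max((sum(diag(R)) - 1) / 2, -1), 1)) * 180 / pi
}

# independent loop-level implementation of the 4-step ensemble fusion rule
fuse_oracle <- function(members, threshold = 0.5) {
  K <- length(members)
  vecs <- lapply(members, function(m) as.vector(if (is.list(m)) m$data else m))
  corr <- matrix(NA_real_, K, K)
  for (i in 1:K) for (j in 1:K)
    corr[i, j] <- suppressWarnings(cor(vecs[[i]], vecs[[j]]))
  n <- numeric(K)
  for (i in 1:K) {
    others <- corr[i, setdiff(1:K, i)]
    thr <- min(0.8, 0.9 * max(others))
    cnt <- 0
    for (j in 1:K) {
      cij <- if (i == j) 1 else corr[i, j]
      if (cij > thr) cnt <- cnt + 1
    }
    n[i] <- cnt
  }
  w <- n / sum(n)
  wsum <- 0
  for (i in 1:K) wsum <- wsum + w[i] * vecs[[i]]
  list(corr = corr, counts = n, weights = w,
       fused = as.integer(wsum >= threshold))
}

random_ensemble <- function(K = 10, dims = c(8, 8, 8), base_seed = 1) {
  base <- array(runif(prod(dims)), dims)
  lapply(seq_len(K), function(i) {
    noise <- array(rnorm(prod(dims), 0, runif(1, 0.01, 0.5)), dims)
    p <- pmin(pmax(base + noise, 0), 1)
    ct_volume(p)
  })
}
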