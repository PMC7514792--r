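# Shared fixtures: synthetic disk images and cached generator scenes.

# Plain bright disk on black canvas (no texture).
makeDiskImage <- function(H, W, cr, cc, r, value = c(200, 120, 60)) {
  d2 <- outer((seq_len(H) - cr)^2, (seq_len(W) - cc)^2, "+")
  inside <- d2 <= r^2
  img <- array(0, c(H, W, 3))
  for (k in 1:3) img[, , k] <- inside * value[k]
  img
}

# One default-size generator scene + its preprocessed form, computed once
# per test run.
fixtureScene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generateFundus(sceneParams(seed = 101))
      cache <<- list(raw = g$image, prep = preprocessFundus(g$image))
    }
    cache
  }
})

# Small reference NSS model pooled from two mildly different scenes.
fixtureReference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      preps <- lapply(c(102, 103), function(s)
        preprocessFundus(generateFundus(sceneParams(seed = s))$image))
      cache <<- buildReferenceModel(preps)
    }
    cache
  }
})
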