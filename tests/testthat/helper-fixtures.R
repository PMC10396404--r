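# Case-study graph documents in the JSON graph format, built in code.

case_study_json <- function(variant = "a") {
  g <- case_study_mdag(variant)
  serialize_mdag(g)
}

chain_mdag <- function() {
  mdag(list(node("a"), node("b"), node("c")),
       list(c("a", "b"), c("b", "c")))
}

collider_mdag <- function() {
  mdag(list(node("a"), node("b"), node("c")),
       list(c("a", "c"), c("b", "c")))
}

case_study_estimand <- function() estimand_regression("Y", "X", c("C", "Z"))

# a small masked dataset with a single incomplete gaussian variable
toy_single_missing <- function(seed = 1, n = 400, n_miss = 120) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  c_ <- rnorm(n)
  y <- 1 + 2 * x + c_ + rnorm(n)
  df <- data.frame(y = y, x = x, c_ = c_)
  df$y[sample(n, n_miss)] <- NA
  df
}

# cached calibrated case-study models, shared across tests in one run
.model_cache <- new.env(parent = emptyenv())
cached_case_study_model <- function(variant, seed = 11, ...) {
  key <- paste(variant, seed, ..., sep = "|")
  if (is.null(.model_cache[[key]]))
    .model_cache[[key]] <- case_study_model(variant, seed = seed, ...)
  .model_cache[[key]]
}
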