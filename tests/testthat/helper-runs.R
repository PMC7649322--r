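# Shared fixtures. Heavy simulations are computed once per test session and
# cached; everything is deterministic, so caching cannot mask failures.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

default_bars <- function() fixture("bars", function() {
  crossing_bars(stimulus_spec(kind = "crossing_bars"), mt_params())
})

bars_trace <- function() fixture("bars_trace", function() {
  run_model(default_bars()$frames, mt_params(), mode = "component",
            store_chi = FALSE)
})

default_plaid <- function() fixture("plaid", function() {
  occluded_plaid(stimulus_spec(kind = "occluded_plaid"), mt_params())
})

plaid_trace <- function(mode) fixture(paste0("plaid_", mode), function() {
  run_model(default_plaid()$frames, mt_params(), mode = mode,
            store_chi = FALSE)
})

default_single_bar <- function() fixture("bar", function() {
  single_bar(stimulus_spec(kind = "single_bar", orientations = 135,
                           directions = 0), mt_params())
})

single_bar_v1 <- function() fixture("bar_v1", function() {
  complex_v1_response(default_single_bar()$frames, mt_params())
})

single_bar_es <- function() fixture("bar_es", function() {
  p <- mt_params()
  vcx <- single_bar_v1()
  ves <- array(0, dim(vcx)[1:3])
  for (t in seq_len(dim(vcx)[4]))
    ves <- endstopped_step(ves, vcx[, , , t], p = p)
  ves
})

bars_v1 <- function() fixture("bars_v1", function() {
  complex_v1_response(default_bars()$frames, mt_params())
})

# small deterministic activity array for property tests
random_activity <- function(H = 16L, W = 16L, N = 8L, seed = 42L) {
  set.seed(seed)
  array(runif(H * W * N), c(H, W, N))
}
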