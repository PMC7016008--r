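# Shared small fixtures, built once per test run.

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_env <- new.env()

cached <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

sheet20 <- function() cached("sheet20", generate_sheet_mesh(20, 20, 500))

coarse_strip <- function() cached("coarse_strip",
                                  generate_sheet_mesh(20, 6, 500))

# a tiny two-triangle strip with hand-checkable geometry
unit_strip <- function() {
  atrial_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
              rbind(c(1, 2, 3), c(2, 4, 3)),
              fiber = matrix(rep(c(1, 0, 0), each = 4), ncol = 3))
}

# constant-vm movie helper
constant_result <- function(n_nodes, value = -80, duration = 1000, dt = 10) {
  times <- seq(0, duration, by = dt)
  structure(list(vm = matrix(value, n_nodes, length(times)), times = times,
                 final_states = NULL, protocol = list(),
                 output_interval = dt, n_steps = 0, wall_time_s = 0),
            class = "simulation_result")
}

# result object wrapping a given vm matrix
wrap_result <- function(vm, times) {
  structure(list(vm = vm, times = times, final_states = NULL,
                 protocol = list(),
                 output_interval = stats::median(diff(times)),
                 n_steps = 0, wall_time_s = 0),
            class = "simulation_result")
}
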