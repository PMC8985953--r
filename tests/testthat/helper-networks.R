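small_params <- function(...) chromatin_params(Dtot = 8L, ...)

paper_ratios <- function(...) chromatin_params(
  alpha = 0.2, alpha_bar = 0.2, alpha_prime = 0.2, Dtot = 8L, ...)

state_index <- function(states, species, value) {
  which(apply(states, 1L, function(s) s[[species]] == value))
}
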