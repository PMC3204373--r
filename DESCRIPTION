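Package: dynsynrl
Title: Reward-Modulated Learning of Hidden Synaptic Parameters in Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates feed-forward networks of leaky integrate-and-fire
    neurons coupled by Tsodyks-Markram dynamic synapses and trains the
    hidden synaptic parameters (utilization increment U_SE, recovery time
    constant tau_rec, facilitation time constant tau_fac) with a
    Hebbian/anti-Hebbian rule driven by the temporal-difference error of an
    episodic reward. The reward is derived from the van Rossum distance
    between the binned network output and a reference spike train, here the
    XOR of the two binned Poisson input trains, so the network learns a
    temporally coded exclusive-OR. Includes spike-train metrics (van Rossum
    distance, Gaussian-filtered maximum cross-correlation, hit rate),
    Poisson stimulus generation, the full episodic training loop with
    per-episode records as tibbles, broom-style tidiers, ggplot2 plot
    methods, and plain-text serialization of spike trains, configurations
    and results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
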