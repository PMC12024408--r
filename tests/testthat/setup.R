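# Report the whole suite even when the stochastic ordering checks fail:
# the default progress reporter stops after 10 failures, which would hide
# later test files behind a red acceptance block.
options(testthat.progress.max_fails = 1000L)
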