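# Shared fixture builders (everything is generated in code at test time).

sine_recording <- function(freq = 10, rate = 1000, duration = 10, amp = 1,
                           phase = 0, label = "O1") {
  t <- (seq_len(round(duration * rate)) - 1) / rate
  multichannel_recording(amp * sin(2 * pi * freq * t + phase), rate, label)
}

# small linear cyclic single-channel config for segment/surrogate tests
quick_config <- function(seed, rate = 200, duration = 30, arp = 0.6,
                         beta = 1, nch = 1) {
  synth_config(sampling_rate_hz = rate, duration_s = duration,
               alpha_rel_power = arp, noise_exponent = beta,
               channel_labels = paste0("ch", seq_len(nch)), seed = seed)
}
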