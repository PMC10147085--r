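# Computed once per test run; calibration is deterministic.
fx <- tau_pet_fixture()
fx_crisp <- crispify(fx$matrix, fx$scale)
repl_cfg <- replication_config()
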