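{"tool":"egonets","version":"0.1.0","command":"parse","options":{"input":"/nonexistent.csv"},"seed":1,"inputs":"/nonexistent.csv","outputs":[],"counts":[],"status":"failed"}
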