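CXXFLAGS = -O3 -funroll-loops -mtune=generic -fPIC
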