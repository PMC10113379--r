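sequence,latitude,longitude
1,36.11878417,140.0937983
2,36.11878317,140.0937943
3,36.11878233,140.0937910
4,36.11878133,140.0937872
5,36.11878050,140.0937835
6,36.11877983,140.0937805
7,36.11877867,140.0937767
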