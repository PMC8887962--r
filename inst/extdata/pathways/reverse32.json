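{
    "name": "reverse32",
    "description": "test pathway: 32-channel channel-reversing stage",
    "stages": [
        {
            "name": "reverse32",
            "mapping": [31, 30, 29, 28, 27, 26, 25, 24, 23, 22, 21, 20, 19, 18, 17, 16, 15, 14, 13, 12, 11, 10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0]
        }
    ]
}
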