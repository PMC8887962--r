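{
    "name": "synthetic-ASSY-156>RHD2164",
    "description": "SYNTHETIC stand-in for an ASSY-156 connector chained to an Intan RHD2164 headstage: deterministic permutations with the right channel count, NOT the vendor-documented wiring",
    "stages": [
        {
            "name": "synthetic-ASSY-156-connector",
            "mapping": [0, 32, 1, 33, 2, 34, 3, 35, 4, 36, 5, 37, 6, 38, 7, 39, 8, 40, 9, 41, 10, 42, 11, 43, 12, 44, 13, 45, 14, 46, 15, 47, 16, 48, 17, 49, 18, 50, 19, 51, 20, 52, 21, 53, 22, 54, 23, 55, 24, 56, 25, 57, 26, 58, 27, 59, 28, 60, 29, 61, 30, 62, 31, 63]
        },
        {
            "name": "synthetic-RHD2164",
            "mapping": [32, 33, 34, 35, 36, 37, 38, 39, 40, 41, 42, 43, 44, 45, 46, 47, 48, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 60, 61, 62, 63, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31]
        }
    ]
}
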