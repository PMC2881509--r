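# Cav-1 (-/-) stromal collagen up-gene membership set, reconstructed from
# the published bold-flag cross-tabulation (the full list is unpublished).
Col11a1
Col5a1
Col1a2
Col3a1
Col4a5
Col6a3
Col6a1
Col9a1
Col4a6
Col1a1
Col5a3
Col16a1
Col24a1
Col4a2
Col18a1
Col9a2
Col14a1
Col23a1
Col11a2
Col2a1
Col27a1
Col4a3
Col19a1
Col4a1
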