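name,printed_value
R1,1.40e8
R2,2.01e9
R3,2.29e9
R4,1.34e8
R5,7.11e9
R6,5.55e7
R7,1.90e8
R8,5.39e9
R9,7.51e7
R10,7.10e7
R11,3.63e7
R12,5.43e9
R13,2.71e9
R14,3.67e9
R15,1.40e9
R16,6.24e7
R17,6.17e7
R18,1.35e8
R19,5.89e7
R20,3.76e7
R21,7.28e7
R22,7.23e7
R23,1.08e8
R24,9.57e7
R25,1.07e8
R26,3.30e7
R27,2.52e7
R28,3.64e7
R29,3.19e7
C1,1.67e-14
C2,3.10e-15
C3,2.54e-15
C4,2.06e-14
C5,5.94e-15
C6,1.13e-13
C7,1.75e-14
C8,7.59e-15
C9,4.07e-14
C10,4.75e-14
C11,4.38e-13
C12,7.46e-15
C13,1.49e-14
C14,8.36e-16
C15,1.56e-15
C16,6.16e-15
C17,1.36e-14
C18,1.22e-14
C19,3.79e-14
C20,2.08e-12
C21,1.67e-13
C22,1.86e-13
C23,9.19e-14
C24,2.75e-13
C25,1.68e-13
C26,6.64e-13
C27,8.32e-13
C28,2.84e-13
C29,3.89e-13
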