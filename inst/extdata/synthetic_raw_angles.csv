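joint,profile,trial,angle_deg
C1-C2,lateral,PCVM,12.04
C2-C3,lateral,PCVM,15.1
C3-C4,lateral,PCVM,14.77
C4-C5,lateral,PCVM,9.59
C5-C6,lateral,PCVM,11.16
C6-C7,lateral,PCVM,12.62
C7-C8,lateral,PCVM,10.97
C8-C9,lateral,PCVM,6.72
C9-C10,lateral,PCVM,19.53
C10-C11,lateral,PCVM,20.5
C11-C12,lateral,PCVM,24.37
C12-C13,lateral,PCVM,3.72
C13-C14,lateral,PCVM,7.74
C14-C15,lateral,PCVM,9.48
C15-C16,lateral,PCVM,11.59
C16-C17,lateral,PCVM,17.4
C17-C18,lateral,PCVM,13.72
C18-C19,lateral,PCVM,9.14
C19-C20,lateral,PCVM,3.45
C20-C21,lateral,PCVM,5.17
C1-C2,dorsal,PCVM,7.38
C2-C3,dorsal,PCVM,5.69
C3-C4,dorsal,PCVM,12.73
C4-C5,dorsal,PCVM,3.64
C5-C6,dorsal,PCVM,1.43
C6-C7,dorsal,PCVM,8.65
C7-C8,dorsal,PCVM,7.37
C8-C9,dorsal,PCVM,1.73
C9-C10,dorsal,PCVM,14.0
C10-C11,dorsal,PCVM,11.44
C11-C12,dorsal,PCVM,7.12
C12-C13,dorsal,PCVM,9.37
C13-C14,dorsal,PCVM,15.34
C14-C15,dorsal,PCVM,11.78
C15-C16,dorsal,PCVM,12.71
C16-C17,dorsal,PCVM,11.89
C17-C18,dorsal,PCVM,6.06
C18-C19,dorsal,PCVM,2.87
C19-C20,dorsal,PCVM,11.64
C20-C21,dorsal,PCVM,8.7
C1-C2,ventral,PCVM,11.27
C2-C3,ventral,PCVM,2.27
C3-C4,ventral,PCVM,9.3
C4-C5,ventral,PCVM,16.61
C5-C6,ventral,PCVM,15.17
C6-C7,ventral,PCVM,15.39
C7-C8,ventral,PCVM,14.19
C8-C9,ventral,PCVM,16.68
C9-C10,ventral,PCVM,9.53
C10-C11,ventral,PCVM,10.46
C11-C12,ventral,PCVM,4.03
C12-C13,ventral,PCVM,16.12
C13-C14,ventral,PCVM,8.34
C14-C15,ventral,PCVM,12.84
C15-C16,ventral,PCVM,13.0
C16-C17,ventral,PCVM,15.72
C17-C18,ventral,PCVM,15.35
C18-C19,ventral,PCVM,10.36
C19-C20,ventral,PCVM,10.85
C20-C21,ventral,PCVM,11.51
C1-C2,lateral,MISM,0.99
C2-C3,lateral,MISM,9.87
C3-C4,lateral,MISM,4.66
C4-C5,lateral,MISM,5.77
C5-C6,lateral,MISM,6.15
C6-C7,lateral,MISM,2.83
C7-C8,lateral,MISM,0.96
C8-C9,lateral,MISM,3.95
C9-C10,lateral,MISM,3.02
C10-C11,lateral,MISM,12.44
C11-C12,lateral,MISM,2.43
C12-C13,lateral,MISM,7.02
C13-C14,lateral,MISM,11.93
C14-C15,lateral,MISM,8.51
C15-C16,lateral,MISM,9.29
C16-C17,lateral,MISM,0.15
C17-C18,lateral,MISM,4.62
C18-C19,lateral,MISM,1.49
C19-C20,lateral,MISM,6.66
C20-C21,lateral,MISM,6.26
C1-C2,dorsal,MISM,10.99
C2-C3,dorsal,MISM,5.53
C3-C4,dorsal,MISM,2.87
C4-C5,dorsal,MISM,9.34
C5-C6,dorsal,MISM,2.84
C6-C7,dorsal,MISM,4.06
C7-C8,dorsal,MISM,1.25
C8-C9,dorsal,MISM,7.66
C9-C10,dorsal,MISM,0.63
C10-C11,dorsal,MISM,9.79
C11-C12,dorsal,MISM,3.95
C12-C13,dorsal,MISM,6.72
C13-C14,dorsal,MISM,3.37
C14-C15,dorsal,MISM,1.92
C15-C16,dorsal,MISM,5.76
C16-C17,dorsal,MISM,0.49
C17-C18,dorsal,MISM,4.71
C18-C19,dorsal,MISM,1.97
C1-C2,ventral,MISM,5.18
C2-C3,ventral,MISM,11.11
C3-C4,ventral,MISM,7.86
C4-C5,ventral,MISM,1.52
C5-C6,ventral,MISM,7.13
C6-C7,ventral,MISM,2.72
C7-C8,ventral,MISM,7.07
C8-C9,ventral,MISM,3.65
C9-C10,ventral,MISM,0.95
C10-C11,ventral,MISM,2.53
C11-C12,ventral,MISM,5.74
C12-C13,ventral,MISM,5.03
C13-C14,ventral,MISM,5.26
C14-C15,ventral,MISM,2.53
C15-C16,ventral,MISM,8.66
C16-C17,ventral,MISM,6.73
C17-C18,ventral,MISM,2.03
C18-C19,ventral,MISM,4.66
C19-C20,ventral,MISM,2.85
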