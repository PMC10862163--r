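id,sire,dam,clutch,dummy
I00001,,,NA,FALSE
I00002,,,NA,FALSE
I00003,,,NA,FALSE
I00004,,,NA,FALSE
I00005,,,NA,FALSE
I00006,,,NA,FALSE
I00007,,,NA,FALSE
I00008,,,NA,FALSE
I00009,,,NA,FALSE
I00010,,,NA,FALSE
I00011,,,NA,FALSE
I00012,,,NA,FALSE
I00013,,,NA,FALSE
I00014,,,NA,FALSE
I00015,,,NA,FALSE
I00016,,,NA,FALSE
I00017,I00011,I00005,I00011 I00005,FALSE
I00018,I00011,I00005,I00011 I00005,FALSE
I00019,I00011,I00005,I00011 I00005,FALSE
I00020,I00003,I00001,I00003 I00001,FALSE
I00021,I00003,I00001,I00003 I00001,FALSE
I00022,I00003,I00001,I00003 I00001,FALSE
I00023,I00015,I00004,I00015 I00004,FALSE
I00024,I00015,I00004,I00015 I00004,FALSE
I00025,I00015,I00004,I00015 I00004,FALSE
I00026,I00009,I00007,I00009 I00007,FALSE
I00027,I00009,I00007,I00009 I00007,FALSE
I00028,I00009,I00007,I00009 I00007,FALSE
I00029,I00006,I00014,I00006 I00014,FALSE
I00030,I00006,I00014,I00006 I00014,FALSE
I00031,I00006,I00014,I00006 I00014,FALSE
I00032,I00010,I00008,I00010 I00008,FALSE
I00033,I00010,I00008,I00010 I00008,FALSE
I00034,I00010,I00008,I00010 I00008,FALSE
I00035,I00016,I00012,I00016 I00012,FALSE
I00036,I00016,I00012,I00016 I00012,FALSE
I00037,I00016,I00012,I00016 I00012,FALSE
I00038,I00013,I00002,I00013 I00002,FALSE
I00039,I00013,I00002,I00013 I00002,FALSE
I00040,I00013,I00002,I00013 I00002,FALSE
I00041,I00037,I00020,I00037 I00020,FALSE
I00042,I00037,I00020,I00037 I00020,FALSE
I00043,I00037,I00020,I00037 I00020,FALSE
I00044,I00031,I00039,I00031 I00039,FALSE
I00045,I00031,I00039,I00031 I00039,FALSE
I00046,I00031,I00039,I00031 I00039,FALSE
I00047,I00025,I00017,I00025 I00017,FALSE
I00048,I00025,I00017,I00025 I00017,FALSE
I00049,I00025,I00017,I00025 I00017,FALSE
I00050,I00019,I00022,I00019 I00022,FALSE
I00051,I00019,I00022,I00019 I00022,FALSE
I00052,I00019,I00022,I00019 I00022,FALSE
I00053,I00033,I00034,I00033 I00034,FALSE
I00054,I00033,I00034,I00033 I00034,FALSE
I00055,I00033,I00034,I00033 I00034,FALSE
I00056,I00035,I00028,I00035 I00028,FALSE
I00057,I00035,I00028,I00035 I00028,FALSE
I00058,I00035,I00028,I00035 I00028,FALSE
I00059,I00038,I00024,I00038 I00024,FALSE
I00060,I00038,I00024,I00038 I00024,FALSE
I00061,I00038,I00024,I00038 I00024,FALSE
I00062,I00036,I00023,I00036 I00023,FALSE
I00063,I00036,I00023,I00036 I00023,FALSE
I00064,I00036,I00023,I00036 I00023,FALSE
I00065,I00027,I00026,I00027 I00026,FALSE
I00066,I00027,I00026,I00027 I00026,FALSE
I00067,I00027,I00026,I00027 I00026,FALSE
I00068,I00029,I00032,I00029 I00032,FALSE
I00069,I00029,I00032,I00029 I00032,FALSE
I00070,I00029,I00032,I00029 I00032,FALSE
I00071,I00040,I00018,I00040 I00018,FALSE
I00072,I00040,I00018,I00040 I00018,FALSE
I00073,I00040,I00018,I00040 I00018,FALSE
I00074,I00021,I00030,I00021 I00030,FALSE
I00075,I00021,I00030,I00021 I00030,FALSE
I00076,I00021,I00030,I00021 I00030,FALSE
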