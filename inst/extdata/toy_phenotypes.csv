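id,y,measurer,year,sex,age
I00001,172.9084509505,M5,2000,F,1
I00001,176.837993651773,M2,2001,F,2
I00001,179.774997311987,M1,2002,F,3
I00002,184.554211291426,M1,2000,F,1
I00002,185.202071319833,M5,2001,F,2
I00003,177.474688030577,M1,2000,M,1
I00004,186.156649331077,M1,2000,F,1
I00005,174.855226599985,M5,2000,F,1
I00005,175.641384715638,M2,2001,F,2
I00006,176.494616768305,M1,2000,M,1
I00007,170.0620905366,M3,2000,F,1
I00007,172.939557733664,M5,2001,F,2
I00007,173.060198574527,M3,2002,F,3
I00008,166.251294218948,M2,2000,F,1
I00008,169.132207362682,M1,2001,F,2
I00009,169.775205630533,M5,2000,M,1
I00009,174.421106670678,M2,2001,M,2
I00009,171.63708009111,M2,2002,M,3
I00010,169.267494554396,M3,2000,M,1
I00010,173.536960116116,M2,2001,M,2
I00011,179.386150729769,M5,2000,M,1
I00012,165.753282839591,M4,2000,F,1
I00012,172.690646603281,M5,2001,F,2
I00013,171.920959361148,M1,2000,M,1
I00013,173.712677588603,M2,2001,M,2
I00014,173.816053014245,M2,2000,F,1
I00014,177.297967100653,M3,2001,F,2
I00014,177.481352949647,M3,2002,F,3
I00015,178.551207311551,M4,2000,M,1
I00016,171.296244959723,M3,2000,M,1
I00016,175.618817978575,M5,2001,M,2
I00016,174.675769735074,M2,2002,M,3
I00017,173.17746787652,M2,2002,F,1
I00017,177.337489499909,M4,2003,F,2
I00018,177.117472195625,M5,2002,F,1
I00018,179.630238888676,M4,2003,F,2
I00018,178.950446426604,M2,2004,F,3
I00019,188.665035441522,M4,2002,M,1
I00020,176.126058075583,M4,2002,F,1
I00020,178.074792824166,M4,2003,F,2
I00021,176.986155386269,M4,2002,M,1
I00021,173.01742423487,M4,2003,M,2
I00022,179.359686904889,M5,2002,F,1
I00022,177.398738809243,M2,2003,F,2
I00022,177.231002897028,M4,2004,F,3
I00023,173.769077882778,M5,2002,F,1
I00023,172.764777919386,M3,2003,F,2
I00024,170.458336646545,M3,2002,F,1
I00024,169.971241831068,M1,2003,F,2
I00025,180.243795125126,M3,2002,M,1
I00025,177.806388064603,M3,2003,M,2
I00025,178.524521207562,M2,2004,M,3
I00026,176.800557752614,M3,2002,F,1
I00026,173.634088444965,M1,2003,F,2
I00026,179.453490492268,M5,2004,F,3
I00027,162.670356206982,M4,2002,M,1
I00027,166.155076564307,M1,2003,M,2
I00027,169.179860275128,M2,2004,M,3
I00028,166.52212937021,M5,2002,F,1
I00029,173.299123698615,M1,2002,M,1
I00029,178.204776030636,M2,2003,M,2
I00030,173.861699322624,M3,2002,F,1
I00030,173.156358122401,M4,2003,F,2
I00031,180.534955483348,M5,2002,M,1
I00032,173.020730798155,M3,2002,F,1
I00032,170.781318475342,M2,2003,F,2
I00032,170.103486877088,M3,2004,F,3
I00033,169.669559869975,M3,2002,M,1
I00033,170.770464216949,M2,2003,M,2
I00034,172.464900553073,M1,2002,F,1
I00034,172.602468382813,M3,2003,F,2
I00034,170.154620961437,M4,2004,F,3
I00035,173.258260799146,M3,2002,M,1
I00035,171.700051586705,M2,2003,M,2
I00035,173.280156743937,M2,2004,M,3
I00036,165.733093815006,M3,2002,M,1
I00036,167.507110656323,M1,2003,M,2
I00037,166.746865715278,M1,2002,M,1
I00037,167.837785790715,M1,2003,M,2
I00038,177.206859539926,M5,2002,M,1
I00038,176.902527872674,M5,2003,M,2
I00039,176.083007937196,M3,2002,F,1
I00039,181.394399518415,M3,2003,F,2
I00040,174.791128379626,M2,2002,M,1
I00040,173.35806490915,M4,2003,M,2
I00041,174.30979992607,M3,2004,M,1
I00041,168.435183111807,M4,2005,M,2
I00042,178.203526635018,M5,2004,F,1
I00042,177.503938548588,M3,2005,F,2
I00043,167.796492977781,M3,2004,F,1
I00044,172.46037703957,M4,2004,M,1
I00044,173.907737183955,M5,2005,M,2
I00045,178.533105302585,M5,2004,M,1
I00045,174.337224760906,M4,2005,M,2
I00045,178.290437793913,M2,2006,M,3
I00046,175.258327653141,M3,2004,F,1
I00047,178.11546855526,M3,2004,F,1
I00047,177.355309315549,M4,2005,F,2
I00047,176.760028766534,M5,2006,F,3
I00048,183.411018630893,M2,2004,M,1
I00049,170.214748510219,M1,2004,M,1
I00050,177.77926155086,M4,2004,M,1
I00051,175.968592276428,M3,2004,M,1
I00051,175.624865817599,M3,2005,M,2
I00052,178.665284251626,M2,2004,F,1
I00053,173.425684254498,M2,2004,F,1
I00054,173.302872493516,M1,2004,M,1
I00055,171.97038700133,M5,2004,M,1
I00056,169.449500839528,M5,2004,F,1
I00057,173.220845736886,M2,2004,M,1
I00057,175.790248761911,M5,2005,M,2
I00057,173.596074273584,M5,2006,M,3
I00058,169.830611245674,M5,2004,F,1
I00059,175.455682675273,M4,2004,F,1
I00059,177.94030064355,M1,2005,F,2
I00059,175.599137754967,M4,2006,F,3
I00060,182.731302369367,M1,2004,F,1
I00061,172.831033401503,M1,2004,M,1
I00062,177.783710202388,M5,2004,F,1
I00062,177.873706874934,M1,2005,F,2
I00063,179.830651066765,M2,2004,M,1
I00063,178.651179740121,M4,2005,M,2
I00063,176.23212305051,M1,2006,M,3
I00064,169.04215322836,M4,2004,M,1
I00064,170.59025406958,M1,2005,M,2
I00064,172.203073443563,M3,2006,M,3
I00065,175.082092864316,M4,2004,F,1
I00065,176.342151383174,M1,2005,F,2
I00066,175.449065752387,M5,2004,F,1
I00066,168.357554094481,M5,2005,F,2
I00066,175.135581480091,M3,2006,F,3
I00067,176.666315307325,M5,2004,M,1
I00067,173.530249680245,M2,2005,M,2
I00067,174.392117442002,M4,2006,M,3
I00068,172.485489449681,M2,2004,M,1
I00068,171.136067099679,M3,2005,M,2
I00068,170.474844915795,M3,2006,M,3
I00069,182.182492475276,M3,2004,F,1
I00069,185.328819307893,M2,2005,F,2
I00069,186.141723736519,M4,2006,F,3
I00070,171.082910889243,M5,2004,F,1
I00070,172.761378748006,M1,2005,F,2
I00070,172.858345582542,M3,2006,F,3
I00071,173.670161712835,M4,2004,F,1
I00071,176.412395860345,M5,2005,F,2
I00071,171.610801762796,M5,2006,F,3
I00072,178.211168293187,M2,2004,M,1
I00072,174.404825604566,M3,2005,M,2
I00073,182.373198431671,M5,2004,F,1
I00074,167.362317126107,M5,2004,M,1
I00074,171.660816656857,M3,2005,M,2
I00075,182.598777004822,M1,2004,F,1
I00075,173.611674847064,M3,2005,F,2
I00075,175.867819818254,M5,2006,F,3
I00076,171.073773209186,M1,2004,M,1
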